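#' Describe the items of a clinical instrument panel
#'
#' An item panel records the identity of each symptom rating that becomes a
#' network node: its id, the instrument it belongs to (SIPS, CAARMS, BPRS,
#' CBCL, MADRS, ...), a human-readable label, and the score bounds of the
#' instrument. The instrument floor (`scale_min`) defines what counts as a
#' "zero" score for prevalence filtering: BPRS items floor at 1, SIPS items
#' at 0.
#'
#' @param item_id character vector of unique item identifiers.
#' @param instrument instrument name, recycled.
#' @param label human-readable label, defaults to `item_id`.
#' @param scale_min,scale_max numeric score bounds, recycled.
#' @return a data frame with one row per item.
#' @export
item_panel <- function(item_id, instrument = "GEN", label = item_id,
                       scale_min = 0, scale_max = 6) {
  if (anyDuplicated(item_id))
    stop("item_id must be unique within a panel")
  panel <- data.frame(item_id = as.character(item_id),
                      instrument = rep_len(as.character(instrument), length(item_id)),
                      label = rep_len(as.character(label), length(item_id)),
                      scale_min = rep_len(as.numeric(scale_min), length(item_id)),
                      scale_max = rep_len(as.numeric(scale_max), length(item_id)),
                      stringsAsFactors = FALSE)
  if (any(panel$scale_min >= panel$scale_max))
    stop("scale_min must be strictly below scale_max")
  panel
}

#' Assemble a two-wave symptom cohort
#'
#' Bundles the two temporal layers of a longitudinal panel: an n x p matrix of
#' baseline item scores, an n x q matrix of follow-up scores, the item panels
#' describing the columns, and per-subject covariates (age at each wave, and
#' sex coded 0/1). All downstream machinery (network construction, embedding,
#' pathway centrality, diffusion prediction) starts from this container.
#'
#' @param baseline,followup numeric score matrices, one row per subject;
#'   columns must match the item panels.
#' @param baseline_items,followup_items item panels (see [item_panel()]); by
#'   default derived from the matrix column names.
#' @param covariates data frame with columns `age_baseline`, `age_followup`
#'   (years) and `sex` (0/1).
#' @param subject_id character vector of subject identifiers.
#' @return an object of class `tmsn_cohort`.
#' @export
cohort <- function(baseline, followup, covariates,
                   baseline_items = NULL, followup_items = NULL,
                   subject_id = NULL) {
  baseline <- as.matrix(baseline)
  followup <- as.matrix(followup)
  baseline_items <- baseline_items %||% item_panel(colnames(baseline))
  followup_items <- followup_items %||% item_panel(colnames(followup))
  subject_id <- as.character(subject_id %||% rownames(baseline) %||%
                               sprintf("S%03d", seq_len(nrow(baseline))))
  colnames(baseline) <- baseline_items$item_id
  colnames(followup) <- followup_items$item_id
  rownames(baseline) <- rownames(followup) <- subject_id
  out <- structure(list(subject_id = subject_id,
                        baseline = baseline, followup = followup,
                        baseline_items = baseline_items,
                        followup_items = followup_items,
                        covariates = as.data.frame(covariates),
                        preprocessing = character(0)),
                   class = "tmsn_cohort")
  validate_cohort(out)
}

#' @rdname cohort
#' @param x a `tmsn_cohort`.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "tmsn_cohort"))
  n <- length(x$subject_id)
  if (n < 3) stop("a cohort needs at least 3 subjects")
  if (nrow(x$baseline) != n || nrow(x$followup) != n)
    stop("score matrices and subject_id disagree on n")
  if (ncol(x$baseline) != nrow(x$baseline_items) ||
      ncol(x$followup) != nrow(x$followup_items))
    stop("matrix column counts do not match the item panels")
  if (anyNA(x$baseline) || anyNA(x$followup) || anyNA(x$covariates))
    stop("cohort contains missing values; load with complete cases only")
  req <- c("age_baseline", "age_followup", "sex")
  miss <- setdiff(req, names(x$covariates))
  if (length(miss))
    stop("covariates lack required column(s): ", paste(miss, collapse = ", "))
  if (length(x$preprocessing) == 0) {   # raw scores: enforce instrument bounds
    for (wave in c("baseline", "followup")) {
      pan <- x[[paste0(wave, "_items")]]
      M <- x[[wave]]
      bad <- which(colSums(M < rep(pan$scale_min, each = n) |
                           M > rep(pan$scale_max, each = n)) > 0)
      if (length(bad))
        stop("scores outside instrument bounds at ", wave, " item(s): ",
             paste(pan$item_id[bad], collapse = ", "))
    }
  }
  invisible(x)
}

#' @export
print.tmsn_cohort <- function(x, ...) {
  cat("Two-wave symptom cohort\n")
  cat(sprintf("  subjects: %d\n", length(x$subject_id)))
  cat(sprintf("  baseline items: %d (%s)\n", nrow(x$baseline_items),
              paste(unique(x$baseline_items$instrument), collapse = ", ")))
  cat(sprintf("  follow-up items: %d (%s)\n", nrow(x$followup_items),
              paste(unique(x$followup_items$instrument), collapse = ", ")))
  if (length(x$preprocessing))
    cat("  preprocessing:", paste(x$preprocessing, collapse = " -> "), "\n")
  invisible(x)
}

#' Read a wide two-wave cohort file
#'
#' Reads a wide CSV/TSV (one row per subject) and assembles a [cohort()]. The
#' schema names the subject-id and covariate columns and maps item ids to the
#' per-wave score columns; with the default `NULL` schema, columns ending in
#' `_t1` / `_t2` are taken as baseline / follow-up items. Subjects with any
#' missing value are dropped (complete-case policy) and the count is reported;
#' `strict = TRUE` turns a missing value into an error instead.
#'
#' @param path path to a delimited text file with a header row.
#' @param schema `NULL`, a list, or the path of a YAML file with entries
#'   `subject_id`, `age_baseline`, `age_followup`, `sex` (column names) and
#'   `baseline` / `followup` (named character vectors, item id -> column).
#'   Optional `instrument`, `scale_min`, `scale_max` describe the panels.
#' @param strict error on missing cells instead of dropping subjects.
#' @param sep field separator, guessed from the extension by default.
#' @return a `tmsn_cohort`; dropped subjects are reported via `message()` and
#'   recorded in the `"drop_log"` attribute.
#' @export
read_cohort <- function(path, schema = NULL, strict = FALSE, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sep %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- read.csv(path, sep = sep, check.names = FALSE,
                  stringsAsFactors = FALSE)
  if (is.character(schema) && length(schema) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML schema requires the 'yaml' package")
    schema <- yaml::read_yaml(schema)
    for (w in c("baseline", "followup")) schema[[w]] <- unlist(schema[[w]])
  }
  schema <- schema %||% .default_schema(names(raw))
  req <- c("subject_id", "age_baseline", "age_followup", "sex")
  for (role in req) {
    col <- schema[[role]] %||% role
    if (!col %in% names(raw))
      stop("schema error: required column '", col, "' (role '", role,
           "') not found")
    schema[[role]] <- col
  }
  for (w in c("baseline", "followup")) {
    missing_cols <- setdiff(schema[[w]], names(raw))
    if (length(missing_cols))
      stop("schema error: ", w, " column(s) not found: ",
           paste(missing_cols, collapse = ", "))
  }
  score_cols <- c(schema$baseline, schema$followup)
  scores <- raw[score_cols]
  non_num <- names(scores)[!vapply(scores, is.numeric, logical(1))]
  if (length(non_num))
    stop("parse error: non-numeric score column(s): ",
         paste(non_num, collapse = ", "))
  used <- raw[c(schema$age_baseline, schema$age_followup, schema$sex,
                score_cols)]
  keep <- complete.cases(used)
  if (!all(keep)) {
    if (strict)
      stop("missing values for subject(s): ",
           paste(raw[[schema$subject_id]][!keep], collapse = ", "))
    message("read_cohort: dropped ", sum(!keep),
            " subject(s) with missing values")
  }
  raw <- raw[keep, , drop = FALSE]
  # a JSON sidecar written by write_cohort() preserves instruments and
  # scale bounds; fall back to the schema's (or generic) panel otherwise
  sidecar <- sub("\\.[a-zA-Z]+$", ".json", path)
  side <- if (sidecar != path && file.exists(sidecar) &&
              requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  mk_panel <- function(ids, wave) {
    sp <- side[[paste0(wave, "_items")]]
    if (!is.null(sp) && all(ids %in% sp$item_id)) {
      i <- match(ids, sp$item_id)
      return(item_panel(ids, instrument = sp$instrument[i],
                        label = sp$label[i], scale_min = sp$scale_min[i],
                        scale_max = sp$scale_max[i]))
    }
    item_panel(ids,
               instrument = schema$instrument %||% "GEN",
               scale_min = schema$scale_min %||% 0,
               scale_max = schema$scale_max %||% 6)
  }
  bl <- as.matrix(raw[schema$baseline])
  fu <- as.matrix(raw[schema$followup])
  colnames(bl) <- names(schema$baseline)
  colnames(fu) <- names(schema$followup)
  out <- cohort(bl, fu,
                covariates = data.frame(
                  age_baseline = raw[[schema$age_baseline]],
                  age_followup = raw[[schema$age_followup]],
                  sex = raw[[schema$sex]]),
                baseline_items = mk_panel(names(schema$baseline), "baseline"),
                followup_items = mk_panel(names(schema$followup), "followup"),
                subject_id = raw[[schema$subject_id]])
  attr(out, "drop_log") <- sum(!keep)
  out
}

.default_schema <- function(cols) {
  bl <- grep("_t1$", cols, value = TRUE)
  fu <- grep("_t2$", cols, value = TRUE)
  if (!length(bl) || !length(fu))
    stop("schema error: no *_t1 / *_t2 item columns found and no schema given")
  list(subject_id = "subject_id", age_baseline = "age_baseline",
       age_followup = "age_followup", sex = "sex",
       baseline = setNames(bl, sub("_t1$", "", bl)),
       followup = setNames(fu, sub("_t2$", "", fu)))
}

#' Write a cohort back to disk
#'
#' Emits the same wide-CSV dialect [read_cohort()] accepts (items as
#' `<id>_t1` / `<id>_t2`) plus, when jsonlite is installed, a JSON sidecar
#' with the item panels and any standardization stats.
#'
#' @param x a `tmsn_cohort`.
#' @param path output CSV path; the sidecar gets extension `.json`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "tmsn_cohort"))
  bl <- x$baseline; colnames(bl) <- paste0(colnames(bl), "_t1")
  fu <- x$followup; colnames(fu) <- paste0(colnames(fu), "_t2")
  df <- data.frame(subject_id = x$subject_id, x$covariates, bl, fu,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    side <- list(baseline_items = x$baseline_items,
                 followup_items = x$followup_items,
                 preprocessing = x$preprocessing,
                 stats = attr(x, "stats"),
                 drop_log = attr(x, "drop_log"))
    jsonlite::write_json(side, sub("\\.[a-zA-Z]+$", ".json", path),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Remove items endorsed by too few subjects
#'
#' Drops items whose fraction of subjects with a score above the instrument
#' floor is strictly below `min_nonzero_frac` (the rule that removes items
#' with a non-zero score in less than 1% of the sample; "non-zero" means
#' above `scale_min`, so instruments flooring at 1 are handled correctly).
#' Because the multilayer network needs the same item set in both temporal
#' layers, an item failing at either wave is removed from both (paired
#' removal); items present in only one wave are filtered individually.
#'
#' @param x a `tmsn_cohort` with raw (untransformed) scores.
#' @param min_nonzero_frac minimum endorsement fraction in `[0, 1]`;
#'   default 0.01.
#' @return the filtered cohort; removed item ids are in the
#'   `"removed_items"` attribute.
#' @export
prevalence_filter <- function(x, min_nonzero_frac = 0.01) {
  stopifnot(inherits(x, "tmsn_cohort"))
  if (min_nonzero_frac < 0 || min_nonzero_frac > 1)
    stop("min_nonzero_frac must be in [0, 1]")
  fail_at <- function(M, panel) {
    frac <- colMeans(M > rep(panel$scale_min, each = nrow(M)))
    panel$item_id[frac < min_nonzero_frac]
  }
  fail_bl <- fail_at(x$baseline, x$baseline_items)
  fail_fu <- fail_at(x$followup, x$followup_items)
  shared <- intersect(x$baseline_items$item_id, x$followup_items$item_id)
  # paired removal: a shared item failing at either wave goes from both
  drop_shared <- intersect(shared, union(fail_bl, fail_fu))
  drop_bl <- union(drop_shared, setdiff(fail_bl, shared))
  drop_fu <- union(drop_shared, setdiff(fail_fu, shared))
  keep_bl <- !(x$baseline_items$item_id %in% drop_bl)
  keep_fu <- !(x$followup_items$item_id %in% drop_fu)
  if (!any(keep_bl) || !any(keep_fu))
    stop("prevalence filter removed every item in a panel")
  x$baseline <- x$baseline[, keep_bl, drop = FALSE]
  x$followup <- x$followup[, keep_fu, drop = FALSE]
  x$baseline_items <- x$baseline_items[keep_bl, , drop = FALSE]
  x$followup_items <- x$followup_items[keep_fu, , drop = FALSE]
  attr(x, "removed_items") <- sort(union(drop_bl, drop_fu))
  validate_cohort(x)
}

#' Regress age and sex out of every item
#'
#' Replaces each item score by the residual of an ordinary least-squares fit
#' on an intercept, age at the corresponding wave, and sex, so that network
#' edges reflect symptom covariation rather than shared demographic trends.
#' When `coefficients` from a previous (training) fit are supplied, they are
#' applied as-is -- this is how a held-out subject is residualized inside the
#' leave-one-out loop. A single-sex (or otherwise singular) design drops the
#' offending regressor with a warning; constant items get all-zero residuals
#' with a warning.
#'
#' @param x a `tmsn_cohort`.
#' @param coefficients `NULL` to fit, or the `"coefficients"` attribute of a
#'   previously residualized cohort.
#' @return the cohort with residual scores; fitted coefficients in the
#'   `"coefficients"` attribute.
#' @export
residualize_covariates <- function(x, coefficients = NULL) {
  stopifnot(inherits(x, "tmsn_cohort"))
  cov <- x$covariates
  out_coef <- list()
  for (wave in c("baseline", "followup")) {
    age <- if (wave == "baseline") cov$age_baseline else cov$age_followup
    X <- cbind(intercept = 1, age = age, sex = cov$sex)
    if (is.null(coefficients)) {
      keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(v) sd(v) > 0))
      if (!all(keep)) {
        warning("singular design: dropping regressor(s) ",
                paste(colnames(X)[!keep], collapse = ", "))
        X <- X[, keep, drop = FALSE]
      }
      if (nrow(X) <= ncol(X))
        stop("too few subjects to residualize (n must exceed the number ",
             "of regressors)")
      Y <- x[[wave]]
      B <- solve(crossprod(X), crossprod(X, Y))
      const <- apply(Y, 2, sd) == 0
      if (any(const))
        warning("constant item(s) at ", wave, ": ",
                paste(colnames(Y)[const], collapse = ", "),
                " (residuals are all zero)")
      out_coef[[wave]] <- list(B = B, columns = colnames(X))
    } else {
      B <- coefficients[[wave]]$B
      X <- X[, coefficients[[wave]]$columns, drop = FALSE]
      out_coef[[wave]] <- coefficients[[wave]]
    }
    x[[wave]] <- x[[wave]] - X %*% B
  }
  x$preprocessing <- c(x$preprocessing, "residualized")
  attr(x, "coefficients") <- out_coef
  x
}

#' Z-score items, optionally with externally supplied statistics
#'
#' Standardizes every item to zero mean and unit standard deviation so that
#' instruments with different score ranges can share one diffusion network.
#' Supplying `stats` from a training fold applies `(x - mean)/sd` with those
#' statistics, which is how held-out subjects are placed on the training
#' scale. The statistics actually used are attached so the transform can be
#' inverted with [destandardize_items()].
#'
#' @param x a `tmsn_cohort`.
#' @param stats `NULL`, or the `"stats"` attribute of a previously
#'   standardized cohort (a list with data frames `baseline` / `followup`).
#' @return the standardized cohort with a `"stats"` attribute.
#' @export
standardize_items <- function(x, stats = NULL) {
  stopifnot(inherits(x, "tmsn_cohort"))
  used <- list()
  for (wave in c("baseline", "followup")) {
    M <- x[[wave]]
    if (is.null(stats)) {
      mu <- colMeans(M)
      sigma <- apply(M, 2, sd)
      if (any(sigma == 0))
        stop("constant item(s) cannot be standardized: ",
             paste(colnames(M)[sigma == 0], collapse = ", "))
    } else {
      st <- stats[[wave]]
      idx <- match(colnames(M), st$item_id)
      if (anyNA(idx)) stop("supplied stats lack item(s): ",
                           paste(colnames(M)[is.na(idx)], collapse = ", "))
      mu <- st$mean[idx]; sigma <- st$sd[idx]
    }
    x[[wave]] <- sweep(sweep(M, 2, mu), 2, sigma, "/")
    used[[wave]] <- data.frame(item_id = colnames(M), mean = mu, sd = sigma,
                               stringsAsFactors = FALSE)
  }
  x$preprocessing <- c(x$preprocessing, "standardized")
  attr(x, "stats") <- used
  x
}

#' @rdname standardize_items
#' @export
destandardize_items <- function(x, stats = attr(x, "stats")) {
  stopifnot(inherits(x, "tmsn_cohort"))
  if (is.null(stats)) stop("no standardization stats available")
  for (wave in c("baseline", "followup")) {
    st <- stats[[wave]]
    idx <- match(colnames(x[[wave]]), st$item_id)
    x[[wave]] <- sweep(sweep(x[[wave]], 2, st$sd[idx], "*"), 2, st$mean[idx],
                       "+")
  }
  x$preprocessing <- setdiff(x$preprocessing, "standardized")
  attr(x, "stats") <- NULL
  x
}

#' Match items across two instrument panels
#'
#' Determines the item set shared by two cohorts that used partly different
#' instruments (e.g. SIPS in one sample and CAARMS in the other, with BPRS in
#' both): items are paired through an explicit correspondence table, and
#' items whose instrument and id coincide verbatim in both panels are shared
#' automatically. Unmatched items are reported as excluded.
#'
#' @param panel_a,panel_b item panels (see [item_panel()]).
#' @param mapping `NULL` or a two-column data frame/matrix of
#'   (`a_item`, `b_item`) id pairs.
#' @return a list with `pairs` (data frame: `a_item`, `b_item`, `source`),
#'   `excluded_a`, `excluded_b` and `n_shared`.
#' @export
align_panels <- function(panel_a, panel_b, mapping = NULL) {
  if (!is.null(mapping)) {
    mapping <- as.data.frame(mapping, stringsAsFactors = FALSE)
    names(mapping) <- c("a_item", "b_item")
    if (anyDuplicated(mapping$a_item) || anyDuplicated(mapping$b_item))
      stop("an item is mapped more than once")
    bad_a <- setdiff(mapping$a_item, panel_a$item_id)
    bad_b <- setdiff(mapping$b_item, panel_b$item_id)
    if (length(bad_a) || length(bad_b))
      stop("mapping references unknown item(s): ",
           paste(c(bad_a, bad_b), collapse = ", "))
  } else {
    mapping <- data.frame(a_item = character(0), b_item = character(0),
                          stringsAsFactors = FALSE)
  }
  key_a <- paste(panel_a$instrument, panel_a$item_id)
  key_b <- paste(panel_b$instrument, panel_b$item_id)
  verbatim <- panel_a$item_id[key_a %in% key_b]
  verbatim <- setdiff(verbatim, c(mapping$a_item, mapping$b_item))
  pairs <- rbind(
    if (nrow(mapping)) cbind(mapping, source = "mapped"),
    if (length(verbatim)) data.frame(a_item = verbatim, b_item = verbatim,
                                     source = "verbatim",
                                     stringsAsFactors = FALSE))
  pairs <- pairs %||% data.frame(a_item = character(0), b_item = character(0),
                                 source = character(0))
  list(pairs = pairs,
       excluded_a = setdiff(panel_a$item_id, pairs$a_item),
       excluded_b = setdiff(panel_b$item_id, pairs$b_item),
       n_shared = nrow(pairs))
}
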