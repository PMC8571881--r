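# Data model: multivariate longitudinal ordinal data in long format,
# age binning, category proportion tables and observed cumulative logits.

#' Define an ordinal outcome
#'
#' An ordinal outcome with `n_categories` ordered levels coded as the
#' consecutive integers `0 .. n_categories - 1`. Category 0 conventionally
#' denotes the lowest level (e.g. "no use") and the highest code the most
#' extreme level (e.g. "daily or near-daily use").
#'
#' @param name Character label, also the column name in long-format data.
#' @param n_categories Integer number of ordered levels (C + 1, at least 2).
#' @param labels Optional character vector of `n_categories` category labels.
#' @return An object of class `outcome_def`.
#' @export
outcome_def <- function(name, n_categories, labels = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  n_categories <- as.integer(n_categories)
  if (is.na(n_categories) || n_categories < 2L) {
    stop("n_categories must be an integer >= 2", call. = FALSE)
  }
  if (!is.null(labels) && length(labels) != n_categories) {
    stop("labels must have length n_categories", call. = FALSE)
  }
  structure(
    list(name = name, n_categories = n_categories, labels = labels),
    class = "outcome_def"
  )
}

#' Construct a validated longitudinal ordinal dataset
#'
#' Wraps a long-format data frame (one row per subject x occasion) after
#' validating outcome codes, occasion uniqueness and ordering. Missing
#' outcome cells are kept as `NA`: missingness is per outcome per occasion,
#' and a row is retained as long as at least one outcome is observed
#' (rows with every outcome missing are dropped with a message).
#'
#' @param df Data frame with columns `subject`, `occasion`, one column per
#'   outcome, and any covariate columns.
#' @param outcomes List of [outcome_def()] objects.
#' @return An object of class `mvord_data`; the validated data frame is in
#'   `$data`, outcome definitions in `$outcomes`.
#' @export
long_ordinal_data <- function(df, outcomes) {
  if (inherits(outcomes, "outcome_def")) outcomes <- list(outcomes)
  stopifnot(is.data.frame(df), length(outcomes) >= 1L)
  need <- c("subject", "occasion", vapply(outcomes, `[[`, "", "name"))
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)
  for (od in outcomes) {
    y <- df[[od$name]]
    bad <- which(!is.na(y) & (y != floor(y) | y < 0 | y > od$n_categories - 1L))
    if (length(bad)) {
      stop(sprintf(
        "outcome '%s': value %s outside 0..%d at row %d",
        od$name, format(y[bad[1]]), od$n_categories - 1L, bad[1]
      ), call. = FALSE)
    }
    df[[od$name]] <- as.integer(y)
  }
  key <- paste(df$subject, df$occasion, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (subject, occasion) pair: ",
         sub("\r", ", occasion ", d), call. = FALSE)
  }
  onames <- vapply(outcomes, `[[`, "", "name")
  all_missing <- rowSums(!is.na(df[, onames, drop = FALSE])) == 0L
  if (any(all_missing)) {
    message(sum(all_missing), " row(s) with every outcome missing dropped")
    df <- df[!all_missing, , drop = FALSE]
  }
  ord <- order(df$subject, df$occasion)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(
    list(data = df, outcomes = outcomes),
    class = "mvord_data"
  )
}

#' @export
print.mvord_data <- function(x, ...) {
  df <- x$data
  cat("Multivariate longitudinal ordinal data\n")
  cat(sprintf("  subjects: %d   rows: %d\n",
              length(unique(df$subject)), nrow(df)))
  for (od in x$outcomes) {
    cat(sprintf("  outcome %-10s %d categories, %d observed cells\n",
                od$name, od$n_categories, sum(!is.na(df[[od$name]]))))
  }
  invisible(x)
}

#' Read a long-format CSV of longitudinal ordinal outcomes
#'
#' @param path Path to a UTF-8 CSV with a header row, one row per
#'   subject x occasion.
#' @param outcomes List of [outcome_def()] objects; their `name`s must match
#'   columns after applying `schema`.
#' @param schema Optional named character vector mapping canonical names to
#'   file column names, e.g. `c(subject = "id", occasion = "wave")`. Columns
#'   named in the schema are renamed; all other columns pass through.
#' @return An `mvord_data` object (see [long_ordinal_data()]).
#' @export
read_long_table <- function(path, outcomes, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    unknown <- setdiff(unname(schema), names(df))
    if (length(unknown)) {
      stop("schema names unknown column(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (canon in names(schema)) {
      names(df)[names(df) == schema[[canon]]] <- canon
    }
  }
  long_ordinal_data(df, outcomes)
}

#' Write a longitudinal ordinal dataset back to CSV
#'
#' Inverse of [read_long_table()]: outcome codes and missing cells
#' round-trip exactly.
#'
#' @param data An `mvord_data` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(data, path) {
  stopifnot(inherits(data, "mvord_data"))
  utils::write.csv(data$data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Half-year (or custom) age binning
#'
#' Bins are half-open intervals `[origin + b*width, origin + (b+1)*width)`
#' for `b = 0 .. n_bins - 1`: an age exactly on an upper edge belongs to the
#' next bin. The default covers ages 13.5 to 26.5 in half-year steps.
#'
#' @param origin Lower edge of the first bin, in years.
#' @param width Bin width in years; must be positive.
#' @param n_bins Number of bins.
#' @return An object of class `age_binning`.
#' @export
age_binning <- function(origin = 13.5, width = 0.5, n_bins = 26L) {
  stopifnot(width > 0, n_bins >= 1)
  structure(
    list(origin = origin, width = width, n_bins = as.integer(n_bins)),
    class = "age_binning"
  )
}

#' Bin ages and derive the relative-age time variable
#'
#' Adds `age_bin` (0-based bin index), a relative-age column equal to
#' `age_bin * width` (years since the origin of the first bin, so the model
#' intercepts refer to the first bin, not a bin midpoint), and a logical
#' `age_out_of_range` flag. Ages below the origin or at/above the last bin
#' edge get `NA` bin and relative age, with the flag set.
#'
#' @param data An `mvord_data` object.
#' @param binning An [age_binning()] object.
#' @param age_col Name of the column holding age in years.
#' @param rel_col Name of the relative-age column to create.
#' @return The `mvord_data` object with the added columns.
#' @export
bin_and_center_age <- function(data, binning = age_binning(),
                               age_col = "age_years", rel_col = "age") {
  stopifnot(inherits(data, "mvord_data"), inherits(binning, "age_binning"))
  df <- data$data
  if (!age_col %in% names(df)) {
    stop("age column '", age_col, "' not found", call. = FALSE)
  }
  age <- df[[age_col]]
  if (all(age < binning$origin, na.rm = TRUE)) {
    stop("all ages fall below the binning origin ", binning$origin,
         call. = FALSE)
  }
  b <- floor((age - binning$origin) / binning$width)
  out <- is.na(b) | b < 0 | b >= binning$n_bins
  b[out] <- NA_real_
  df$age_bin <- as.integer(b)
  df[[rel_col]] <- b * binning$width
  df$age_out_of_range <- out
  data$data <- df
  data
}

#' Category counts and proportions by group
#'
#' For each combination of the grouping variables and each outcome, counts
#' observations per category 0..C and converts them to proportions. The
#' denominator for an outcome excludes cells missing for that outcome, so
#' mixed missingness does not distort other outcomes. Group combinations
#' with no observations for an outcome are retained with zero counts; their
#' proportions are `NaN` and flagged `undefined = TRUE`.
#'
#' @param data An `mvord_data` object.
#' @param by Character vector of grouping column names (may be empty).
#' @return A data frame of class `proportion_table` with columns: the
#'   grouping variables, `outcome`, `category`, `count`, `total`,
#'   `proportion`, `undefined`.
#' @export
category_proportions <- function(data, by = character()) {
  stopifnot(inherits(data, "mvord_data"))
  df <- data$data
  miss <- setdiff(by, names(df))
  if (length(miss)) {
    stop("unknown grouping column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  pieces <- list()
  for (od in data$outcomes) {
    C1 <- od$n_categories
    y <- factor(df[[od$name]], levels = 0:(C1 - 1L))
    if (length(by)) {
      gvars <- lapply(by, function(v) factor(df[[v]]))
      names(gvars) <- by
      tab <- table(c(gvars, list(category = y)), useNA = "no")
      counts <- as.data.frame(tab, stringsAsFactors = FALSE)
      names(counts)[ncol(counts)] <- "count"
    } else {
      tab <- table(category = y)
      counts <- as.data.frame(tab, stringsAsFactors = FALSE)
      names(counts)[2] <- "count"
    }
    counts$category <- as.integer(as.character(counts$category))
    counts$outcome <- od$name
    key <- if (length(by)) {
      interaction(counts[by], drop = FALSE)
    } else factor(rep(1, nrow(counts)))
    tot <- tapply(counts$count, key, sum)
    counts$total <- as.vector(tot[as.character(key)])
    counts$proportion <- ifelse(counts$total > 0,
                                counts$count / counts$total, NaN)
    counts$undefined <- counts$total == 0
    pieces[[od$name]] <- counts[, c(by, "outcome", "category",
                                    "count", "total", "proportion",
                                    "undefined")]
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("proportion_table", "data.frame")
  attr(out, "by") <- by
  out
}

#' Observed cumulative logits from a proportion table
#'
#' For each group and outcome computes, for cutpoints c = 0..C-1, the
#' observed cumulative logit log\[P(Y <= c) / (1 - P(Y <= c))\]. Cells whose
#' cumulative proportion is exactly 0 or 1 yield -Inf/+Inf in `logit`; a
#' continuity-corrected version (0.5 added to both sides of the binary
#' collapse at each cutpoint: `log((cum + 0.5) / (n - cum + 0.5))`) is
#' always reported alongside in `corrected_logit`, never silently
#' substituted.
#'
#' @param props A `proportion_table` from [category_proportions()].
#' @return A data frame with the grouping variables, `outcome`, `cutpoint`,
#'   `comparison`, `cum_count`, `cum_proportion`, `logit`, `corrected_logit`.
#' @export
observed_cumulative_logits <- function(props) {
  stopifnot(inherits(props, "proportion_table"))
  by <- attr(props, "by")
  keyvars <- c(by, "outcome")
  key <- interaction(props[keyvars], drop = TRUE)
  pieces <- lapply(split(props, key), function(g) {
    g <- g[order(g$category), , drop = FALSE]
    C1 <- nrow(g)
    n <- sum(g$count)
    cum <- cumsum(g$count)[-C1]
    p <- if (n > 0) cum / n else rep(NaN, C1 - 1L)
    lgt <- log(p / (1 - p))
    clgt <- log((cum + 0.5) / (n - cum + 0.5))
    cc <- seq_len(C1 - 1L) - 1L
    cmp <- vapply(cc, function(c) {
      paste0(paste(0:c, collapse = ","), " vs ",
             paste((c + 1):(C1 - 1L), collapse = ","))
    }, "")
    out <- g[rep(1L, C1 - 1L), keyvars, drop = FALSE]
    out$cutpoint <- cc
    out$comparison <- cmp
    out$cum_count <- cum
    out$cum_proportion <- p
    out$logit <- lgt
    out$corrected_logit <- clgt
    out
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("cumulative_logit_table", "data.frame")
  attr(out, "by") <- by
  out
}
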