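# Containers for per-subject concordance indicators and their reductions.

#' Reader pair index for m readers
#'
#' Lexicographic ordering of unordered reader pairs (j, j') with j < j',
#' i.e. (1,2), (1,3), ..., (1,m), (2,3), ...  This ordering defines the
#' column layout of the pairwise indicator matrix everywhere in the package.
#'
#' @param m number of readers (>= 2).
#' @return integer matrix with columns `j`, `jp` and `m*(m-1)/2` rows.
#' @export
reader_pairs <- function(m) {
  m <- as.integer(m)
  if (is.na(m) || m < 2L) stop("need at least m = 2 readers", call. = FALSE)
  out <- do.call(rbind, lapply(seq_len(m - 1L), function(j) {
    cbind(j = j, jp = (j + 1L):m)
  }))
  out
}

.check_binary <- function(x, what) {
  if (!all(x %in% c(0, 1))) {
    stop(sprintf("%s must contain only 0/1 values", what), call. = FALSE)
  }
}

#' Objective-1 concordance data
#'
#' Bundles the binary concordance indicators for a trial in which each of
#' `n` subjects is read by one AI-based device and `m` radiologists:
#' `r_indicators[i, k] = 1` if the two radiologists of pair `k` (ordered as
#' in [reader_pairs()]) agree on subject `i`, and `s_indicators[i, j] = 1`
#' if radiologist `j` agrees with the device.  Per-subject concordance
#' scores are the row means `r_i` and `s_i`.
#'
#' @param r_indicators n x m(m-1)/2 binary matrix of radiologist-pair
#'   agreement indicators.
#' @param s_indicators n x m binary matrix of device-radiologist agreement
#'   indicators.
#' @return object of class `concordance_data1` with elements `n`, `m`,
#'   `r_indicators`, `s_indicators`, `r_i`, `s_i`.
#' @seealso [indicators_from_readings()], [estimate_pr()], [estimate_ps()]
#' @export
concordance_data1 <- function(r_indicators, s_indicators) {
  r <- as.matrix(r_indicators)
  s <- as.matrix(s_indicators)
  storage.mode(r) <- "double"
  storage.mode(s) <- "double"
  n <- nrow(s)
  m <- ncol(s)
  if (n < 1L) stop("empty data: need at least one subject", call. = FALSE)
  if (m < 2L) stop("need at least m = 2 radiologists", call. = FALSE)
  if (nrow(r) != n) {
    stop("r_indicators and s_indicators must have the same number of rows",
         call. = FALSE)
  }
  if (ncol(r) != m * (m - 1L) / 2L) {
    stop(sprintf("r_indicators must have m(m-1)/2 = %d columns, found %d",
                 m * (m - 1L) / 2L, ncol(r)), call. = FALSE)
  }
  .check_binary(r, "r_indicators")
  .check_binary(s, "s_indicators")
  structure(
    list(n = n, m = m, r_indicators = r, s_indicators = s,
         r_i = rowMeans(r), s_i = rowMeans(s)),
    class = "concordance_data1"
  )
}

#' Objective-2 concordance data
#'
#' Indicators for a trial comparing device concordance with `m` senior and
#' `m` junior radiologists: `x_indicators[i, j] = 1` if senior radiologist
#' `j` agrees with the device on subject `i`; `y_indicators` likewise for
#' junior radiologists.
#'
#' @param x_indicators n x m binary matrix (device vs senior).
#' @param y_indicators n x m binary matrix (device vs junior).
#' @return object of class `concordance_data2` with elements `n`, `m`,
#'   `x_indicators`, `y_indicators`, `x_i`, `y_i`.
#' @export
concordance_data2 <- function(x_indicators, y_indicators) {
  x <- as.matrix(x_indicators)
  y <- as.matrix(y_indicators)
  storage.mode(x) <- "double"
  storage.mode(y) <- "double"
  n <- nrow(x)
  m <- ncol(x)
  if (n < 1L) stop("empty data: need at least one subject", call. = FALSE)
  if (m < 2L) stop("need at least m = 2 radiologists per group", call. = FALSE)
  if (nrow(y) != n || ncol(y) != m) {
    stop("x_indicators and y_indicators must have identical dimensions ",
         "(equal group sizes)", call. = FALSE)
  }
  .check_binary(x, "x_indicators")
  .check_binary(y, "y_indicators")
  structure(
    list(n = n, m = m, x_indicators = x, y_indicators = y,
         x_i = rowMeans(x), y_i = rowMeans(y)),
    class = "concordance_data2"
  )
}

#' @export
print.concordance_data1 <- function(x, ...) {
  cat(sprintf("Objective-1 concordance data: n = %d subjects, m = %d radiologists\n",
              x$n, x$m))
  cat(sprintf("  p^r = %.4f (radiologist-radiologist), p^s = %.4f (device-radiologist)\n",
              mean(x$r_i), mean(x$s_i)))
  invisible(x)
}

#' @export
print.concordance_data2 <- function(x, ...) {
  cat(sprintf("Objective-2 concordance data: n = %d subjects, m = %d per group\n",
              x$n, x$m))
  cat(sprintf("  p^x = %.4f (device-senior), p^y = %.4f (device-junior)\n",
              mean(x$x_i), mean(x$y_i)))
  invisible(x)
}

# canonical label normalization: agreement = exact label match after
# trimming whitespace and case folding
.normalize_label <- function(x) tolower(trimws(as.character(x)))

.readings_columns <- c("subject_id", "reader_id", "reader_role",
                       "classification", "value")

#' Read a long-format readings table from CSV
#'
#' Expects a UTF-8 comma-separated file with header
#' `subject_id,reader_id,reader_role,classification,value`: one row per
#' (subject, reader, lexicon classification) reading.  `reader_role` is
#' `device` plus `radiologist` (Objective 1) or `senior`/`junior`
#' (Objective 2).
#'
#' @param path CSV file path.
#' @return data frame with the five columns above.
#' @export
read_readings <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop(sprintf("cannot parse readings file %s: %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  missing <- setdiff(.readings_columns, names(df))
  if (length(missing)) {
    stop(sprintf("readings file %s lacks required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    stop(sprintf("readings file %s contains no rows", path), call. = FALSE)
  }
  df[.readings_columns]
}

# value of the single device reading per subject, subjects in sorted order
.device_values <- function(df, subjects) {
  dev <- df[df$reader_role == "device", , drop = FALSE]
  vals <- vapply(subjects, function(s) {
    v <- dev$value[dev$subject_id == s]
    if (length(v) == 0L) {
      stop(sprintf("missing device reading for subject '%s'", s), call. = FALSE)
    }
    if (length(v) > 1L) {
      stop(sprintf("multiple device readings for subject '%s'", s), call. = FALSE)
    }
    v
  }, character(1))
  .normalize_label(vals)
}

# n x m matrix of normalized labels for one reader role, readers sorted by id
.reader_matrix <- function(df, subjects, role) {
  sub <- df[df$reader_role == role, , drop = FALSE]
  readers <- sort(unique(sub$reader_id))
  if (length(readers) < 2L) {
    stop(sprintf("need at least 2 readers with role '%s', found %d",
                 role, length(readers)), call. = FALSE)
  }
  mat <- matrix(NA_character_, length(subjects), length(readers),
                dimnames = list(subjects, readers))
  for (k in seq_len(nrow(sub))) {
    mat[sub$subject_id[k], sub$reader_id[k]] <- sub$value[k]
  }
  miss <- which(is.na(mat), arr.ind = TRUE)
  if (nrow(miss)) {
    stop(sprintf("missing reading for subject '%s', reader '%s' (role '%s')",
                 subjects[miss[1, 1]], readers[miss[1, 2]], role), call. = FALSE)
  }
  matrix(.normalize_label(mat), nrow(mat), ncol(mat),
         dimnames = dimnames(mat))
}

#' Concordance indicators from raw categorical readings
#'
#' Reduces a long-format table of categorical readings for one lexicon
#' classification (e.g. BI-RADS "Shape") to binary agreement indicators.
#' Two readings concur iff they carry the same category label after
#' whitespace trimming and case folding; there is no partial credit for
#' adjacent categories.  Reader pair order follows [reader_pairs()] over
#' readers sorted by id, so indicator layouts are reproducible.
#'
#' @param readings data frame as returned by [read_readings()].
#' @param classification which lexicon classification to analyze.
#' @param objective 1 (device + radiologists) or 2 (device + senior/junior
#'   groups of equal size).
#' @return [concordance_data1()] or [concordance_data2()] object.
#' @examples
#' df <- data.frame(
#'   subject_id = "p1",
#'   reader_id = c("dev", "r1", "r2", "r3"),
#'   reader_role = c("device", "radiologist", "radiologist", "radiologist"),
#'   classification = "Shape",
#'   value = c("oval", "oval", "oval", "round")
#' )
#' d <- indicators_from_readings(df, "Shape")
#' d$r_i  # 1/3: only the (r1, r2) pair agrees
#' d$s_i  # 2/3: r1 and r2 agree with the device
#' @export
indicators_from_readings <- function(readings, classification, objective = 1) {
  objective <- match.arg(as.character(objective), c("1", "2"))
  missing_cols <- setdiff(.readings_columns, names(readings))
  if (length(missing_cols)) {
    stop(sprintf("readings table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  avail <- sort(unique(as.character(readings$classification)))
  if (!classification %in% avail) {
    stop(sprintf("classification '%s' not present; available: %s",
                 classification, paste(avail, collapse = ", ")), call. = FALSE)
  }
  df <- readings[readings$classification == classification, , drop = FALSE]
  df$subject_id <- as.character(df$subject_id)
  df$reader_id <- as.character(df$reader_id)
  df$reader_role <- .normalize_label(df$reader_role)
  subjects <- sort(unique(df$subject_id))
  dup <- duplicated(df[c("subject_id", "reader_id")])
  if (any(dup)) {
    stop(sprintf("duplicate reading for subject '%s', reader '%s'",
                 df$subject_id[dup][1], df$reader_id[dup][1]), call. = FALSE)
  }
  device <- .device_values(df, subjects)

  if (objective == "1") {
    lab <- .reader_matrix(df, subjects, "radiologist")
    m <- ncol(lab)
    pr_idx <- reader_pairs(m)
    r <- matrix(0, length(subjects), nrow(pr_idx))
    for (k in seq_len(nrow(pr_idx))) {
      r[, k] <- as.numeric(lab[, pr_idx[k, 1]] == lab[, pr_idx[k, 2]])
    }
    s <- matrix(as.numeric(lab == device), nrow(lab), m)
    colnames(r) <- sprintf("r_%d_%d", pr_idx[, 1], pr_idx[, 2])
    colnames(s) <- sprintf("s_%d", seq_len(m))
    concordance_data1(r, s)
  } else {
    xs <- .reader_matrix(df, subjects, "senior")
    ys <- .reader_matrix(df, subjects, "junior")
    if (ncol(xs) != ncol(ys)) {
      stop(sprintf("senior and junior groups must have equal size (found %d vs %d)",
                   ncol(xs), ncol(ys)), call. = FALSE)
    }
    x <- matrix(as.numeric(xs == device), nrow(xs), ncol(xs))
    y <- matrix(as.numeric(ys == device), nrow(ys), ncol(ys))
    colnames(x) <- sprintf("x_%d", seq_len(ncol(x)))
    colnames(y) <- sprintf("y_%d", seq_len(ncol(y)))
    concordance_data2(x, y)
  }
}

#' Overall concordance rate estimators
#'
#' `estimate_pr()` returns the estimated radiologist-radiologist
#' concordance rate, the mean of the per-subject scores `r_i`;
#' `estimate_ps()` the device-radiologist rate (mean of `s_i`);
#' `estimate_px_py()` the device-senior and device-junior rates.  All are
#' unbiased GEE working-independence estimators of the corresponding
#' population rates.
#'
#' @param data a `concordance_data1` (`estimate_pr`, `estimate_ps`) or
#'   `concordance_data2` (`estimate_px_py`) object.
#' @return a rate in `[0, 1]`; `estimate_px_py()` returns a named vector
#'   `c(px = ..., py = ...)`.
#' @export
estimate_pr <- function(data) {
  stopifnot(inherits(data, "concordance_data1"))
  mean(data$r_i)
}

#' @rdname estimate_pr
#' @export
estimate_ps <- function(data) {
  stopifnot(inherits(data, "concordance_data1"))
  mean(data$s_i)
}

#' @rdname estimate_pr
#' @export
estimate_px_py <- function(data) {
  stopifnot(inherits(data, "concordance_data2"))
  c(px = mean(data$x_i), py = mean(data$y_i))
}

#' Write / read indicator matrices as wide CSV
#'
#' One row per subject; columns are the indicator labels (`r_j_jp`, `s_j`
#' for Objective 1; `x_j`, `y_j` for Objective 2) preceded by a `subject`
#' index column.  The files written by [write_indicators()] round-trip
#' through [read_indicators()].
#'
#' @param data concordance data object.
#' @param path output CSV path.
#' @export
write_indicators <- function(data, path) {
  if (inherits(data, "concordance_data1")) {
    wide <- cbind(subject = seq_len(data$n), data$r_indicators, data$s_indicators)
  } else if (inherits(data, "concordance_data2")) {
    wide <- cbind(subject = seq_len(data$n), data$x_indicators, data$y_indicators)
  } else {
    stop("data must be a concordance_data1 or concordance_data2 object",
         call. = FALSE)
  }
  write.csv(as.data.frame(wide), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_indicators
#' @param objective 1 or 2, declaring the indicator layout of the file.
#' @export
read_indicators <- function(path, objective = 1) {
  objective <- match.arg(as.character(objective), c("1", "2"))
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop(sprintf("empty indicator file: %s", path), call. = FALSE)
  df$subject <- NULL
  nm <- names(df)
  if (objective == "1") {
    rcols <- grep("^r_", nm)
    scols <- grep("^s_", nm)
    if (!length(rcols) || !length(scols)) {
      stop(sprintf("file %s does not look like Objective-1 indicators (need r_*/s_* columns)",
                   path), call. = FALSE)
    }
    concordance_data1(as.matrix(df[rcols]), as.matrix(df[scols]))
  } else {
    xcols <- grep("^x_", nm)
    ycols <- grep("^y_", nm)
    if (!length(xcols) || !length(ycols)) {
      stop(sprintf("file %s does not look like Objective-2 indicators (need x_*/y_* columns)",
                   path), call. = FALSE)
    }
    concordance_data2(as.matrix(df[xcols]), as.matrix(df[ycols]))
  }
}

#' Simulate a raw categorical readings table
#'
#' Simple fixture generator for input/output testing: every reader
#' (including the device) draws i.i.d. category labels from `categories`
#' with probabilities `probs`.  It makes no attempt to induce a particular
#' indicator correlation structure (simulating raw readings consistent
#' with given indicator correlations is underdetermined); use
#' [simulate_dataset()] to generate indicators with controlled
#' correlations.
#'
#' @param n number of subjects.
#' @param m radiologists (objective 1) or per-experience-group readers
#'   (objective 2).
#' @param categories character vector of category labels.
#' @param objective 1 or 2.
#' @param probs category probabilities (default uniform).
#' @param classification classification name for the output table.
#' @param seed optional RNG seed.
#' @return long-format readings data frame (see [read_readings()]).
#' @export
simulate_readings <- function(n, m, categories = c("oval", "round", "irregular"),
                              objective = 1, probs = NULL,
                              classification = "Shape", seed = NULL) {
  objective <- match.arg(as.character(objective), c("1", "2"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(probs)) probs <- rep(1 / length(categories), length(categories))
  roles <- if (objective == "1") {
    data.frame(reader_id = c("device", sprintf("rad%02d", seq_len(m))),
               reader_role = c("device", rep("radiologist", m)))
  } else {
    data.frame(reader_id = c("device", sprintf("sen%02d", seq_len(m)),
                             sprintf("jun%02d", seq_len(m))),
               reader_role = c("device", rep("senior", m), rep("junior", m)))
  }
  subj <- sprintf("subj%04d", seq_len(n))
  grid <- expand.grid(subject_id = subj, reader_id = roles$reader_id,
                      stringsAsFactors = FALSE)
  grid$reader_role <- roles$reader_role[match(grid$reader_id, roles$reader_id)]
  grid$classification <- classification
  grid$value <- sample(categories, nrow(grid), replace = TRUE, prob = probs)
  grid[order(grid$subject_id, grid$reader_id),
       .readings_columns]
}
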