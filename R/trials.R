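#' Construct an irradiation-trial dataset
#'
#' A `trial_dataset` holds one row per irradiation attempt: the emitted
#' laser power (mW), the irradiation duration (s), the manually measured
#' target-cell area (µm², possibly missing), a free-text tissue label and
#' one of six categorical outcomes describing where VENUS (recombination)
#' and PI (death) signals appeared.
#'
#' @param records data frame with columns `trial_id`, `power_mw`,
#'   `duration_s`, `cell_size_um2`, `tissue`, `outcome` (and optionally
#'   `c_size`, the normalized cell size added by [normalize_cell_size()]).
#' @param size_stats optional list with elements `mean` and `sd`, recorded
#'   when size normalization has been applied.
#' @return object of class `trial_dataset`.
#' @seealso [read_trials()], [simulate_trials()]
#' @export
trial_dataset <- function(records, size_stats = NULL) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(TRIALS_HEADER, names(records))
  if (length(missing_cols) > 0L) {
    stop("records is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  records$outcome <- as.character(records$outcome)
  bad <- which(!records$outcome %in% OUTCOME_LEVELS)
  if (length(bad) > 0L) {
    stop("unknown outcome category '", records$outcome[bad[1L]],
         "' in row ", bad[1L])
  }
  .check_positive(records$power_mw, "power_mw", allow_na = FALSE)
  .check_positive(records$duration_s, "duration_s", allow_na = FALSE)
  .check_positive(records$cell_size_um2, "cell_size_um2", allow_na = TRUE)
  if (!is.null(size_stats)) {
    stopifnot(is.list(size_stats), is.numeric(size_stats$mean),
              is.numeric(size_stats$sd), size_stats$sd > 0)
  }
  structure(list(records = records, size_stats = size_stats),
            class = "trial_dataset")
}

.check_positive <- function(x, name, allow_na) {
  if (!is.numeric(x)) stop(name, " must be numeric")
  bad <- if (allow_na) which(!is.na(x) & x <= 0) else which(is.na(x) | x <= 0)
  if (length(bad) > 0L) {
    stop(name, " must be strictly positive (row ", bad[1L], ")")
  }
  invisible(TRUE)
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat("Irradiation trials: ", nrow(x$records), " records\n", sep = "")
  if (nrow(x$records) > 0L) {
    cat("  power range: ", min(x$records$power_mw), "-",
        max(x$records$power_mw), " mW; duration(s): ",
        paste(unique(x$records$duration_s), collapse = ", "), " s\n", sep = "")
    print(table(outcome = x$records$outcome))
  }
  if (!is.null(x$size_stats)) {
    cat(sprintf("  normalized sizes: mean %.6g um^2, sd %.6g um^2\n",
                x$size_stats$mean, x$size_stats$sd))
  }
  invisible(x)
}

#' @export
as.data.frame.trial_dataset <- function(x, ...) x$records

#' Number of trials in a dataset
#' @param dataset a [trial_dataset()].
#' @return integer count.
#' @export
n_trials <- function(dataset) nrow(dataset$records)

#' Read an irradiation-trial CSV
#'
#' The file must be UTF-8 CSV with header exactly
#' `trial_id,power_mw,duration_s,cell_size_um2,tissue,outcome`; `outcome`
#' is one of the six category codes and an empty `cell_size_um2` field is
#' read as missing.
#'
#' @param path file to read.
#' @return a [trial_dataset()].
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  if (!identical(header, TRIALS_HEADER)) {
    stop("unexpected header: expected '",
         paste(TRIALS_HEADER, collapse = ","), "'")
  }
  raw <- read.csv(path, colClasses = "character", na.strings = NULL,
                  check.names = FALSE)
  if (nrow(raw) == 0L) {
    rec <- data.frame(trial_id = character(), power_mw = numeric(),
                      duration_s = numeric(), cell_size_um2 = numeric(),
                      tissue = character(), outcome = character(),
                      stringsAsFactors = FALSE)
    return(trial_dataset(rec))
  }
  num_field <- function(col, name, allow_empty) {
    x <- trimws(raw[[col]])
    out <- rep(NA_real_, length(x))
    empty <- x == ""
    if (any(empty) && !allow_empty) {
      stop("empty ", name, " in row ", which(empty)[1L])
    }
    out[!empty] <- suppressWarnings(as.numeric(x[!empty]))
    bad <- which(!empty & is.na(out))
    if (length(bad) > 0L) {
      stop("cannot parse ", name, " '", x[bad[1L]], "' in row ", bad[1L])
    }
    bad <- which(!is.na(out) & out <= 0)
    if (length(bad) > 0L) {
      stop(name, " must be strictly positive in row ", bad[1L])
    }
    out
  }
  rec <- data.frame(
    trial_id = raw$trial_id,
    power_mw = num_field("power_mw", "power_mw", allow_empty = FALSE),
    duration_s = num_field("duration_s", "duration_s", allow_empty = FALSE),
    cell_size_um2 = num_field("cell_size_um2", "cell_size_um2",
                              allow_empty = TRUE),
    tissue = raw$tissue,
    outcome = raw$outcome,
    stringsAsFactors = FALSE
  )
  trial_dataset(rec)
}

#' Write an irradiation-trial CSV
#'
#' Numeric fields are written with enough digits that
#' `read_trials(write_trials(d))` round-trips losslessly; a missing cell
#' size is written as an empty field.
#'
#' @param dataset a [trial_dataset()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_trials <- function(dataset, path) {
  stopifnot(inherits(dataset, "trial_dataset"))
  rec <- dataset$records
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  out <- data.frame(
    trial_id = rec$trial_id,
    power_mw = fmt(rec$power_mw),
    duration_s = fmt(rec$duration_s),
    cell_size_um2 = fmt(rec$cell_size_um2),
    tissue = rec$tissue,
    outcome = rec$outcome,
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) stop("cannot write '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}

#' Encode a categorical outcome as the four binary endpoints
#'
#' Maps each of the six outcome categories to the event indicators behind
#' the per-trial probabilities: `target` (VENUS in the irradiated cell),
#' `neighboring` (VENUS in at least one other cell), `local`
#' (`target OR neighboring`) and `death` (any PI-positive cell).  The
#' VENUS bits are marginal: a category records VENUS presence in each
#' compartment regardless of the other, which is the reading under which
#' the union identity for the local endpoint holds.
#'
#' @param outcome character vector of category codes.
#' @return data frame with integer columns `target`, `neighboring`,
#'   `local`, `death`, one row per input element.
#' @export
encode_endpoints <- function(outcome) {
  outcome <- as.character(outcome)
  bad <- which(!outcome %in% OUTCOME_LEVELS)
  if (length(bad) > 0L) {
    stop("unknown outcome category: '", outcome[bad[1L]], "'")
  }
  map <- data.frame(
    row.names = OUTCOME_LEVELS,
    target      = c(0L, 1L, 1L, 0L, 0L, 1L),
    neighboring = c(0L, 0L, 1L, 1L, 0L, 1L),
    death       = c(0L, 0L, 0L, 0L, 1L, 1L)
  )
  out <- map[outcome, , drop = FALSE]
  out$local <- as.integer(out$target | out$neighboring)
  rownames(out) <- NULL
  out[, ENDPOINTS]
}

#' Extract one binary endpoint from a dataset
#'
#' @param dataset a [trial_dataset()].
#' @param endpoint one of `"target"`, `"neighboring"`, `"local"`, `"death"`.
#' @return integer 0/1 vector, one element per trial.
#' @export
endpoint_outcomes <- function(dataset, endpoint) {
  endpoint <- match.arg(endpoint, ENDPOINTS)
  encode_endpoints(dataset$records$outcome)[[endpoint]]
}

#' Normalize target-cell sizes
#'
#' Adds a `c_size` column holding the z-scored cell area,
#' `c = (size - mean) / sd` with the sample (n-1) standard deviation, and
#' records `mean` and `sd` in `size_stats` so that raw-µm² predictions can
#' be reproduced later.  At `c = 0` the size-covariate models reduce to
#' their size-ignored counterparts, i.e. the size-ignored fits describe a
#' cell of average area.  Records without a measured size keep `c_size`
#' missing.
#'
#' @param dataset a [trial_dataset()].
#' @return the dataset with `c_size` added and `size_stats` set.
#' @export
normalize_cell_size <- function(dataset) {
  stopifnot(inherits(dataset, "trial_dataset"))
  sizes <- dataset$records$cell_size_um2
  present <- !is.na(sizes)
  if (sum(present) < 2L) {
    stop("need at least 2 records with a measured cell size")
  }
  m <- mean(sizes[present])
  s <- sd(sizes[present])
  if (!is.finite(s) || s == 0) {
    stop("degenerate cell-size variance: all measured sizes identical")
  }
  dataset$records$c_size <- (sizes - m) / s
  dataset$size_stats <- list(mean = m, sd = s)
  dataset
}

#' Tabulate outcome categories by laser-power bin
#'
#' Bins are half-open on the right, `[lo, hi)`, except the last, which is
#' closed, so consecutive printed bin labels cover the power axis without
#' ambiguity.
#'
#' @param dataset a [trial_dataset()].
#' @param bin_edges increasing numeric vector of k+1 boundaries defining k
#'   bins.  Every observed power must fall in some bin.
#' @return data frame with columns `bin_lo`, `bin_hi`, `n`, one count
#'   column per outcome category, and one `prop_<category>` column per
#'   category (proportions are `NA` in empty bins).
#' @export
bin_frequencies <- function(dataset, bin_edges) {
  stopifnot(inherits(dataset, "trial_dataset"),
            is.numeric(bin_edges), length(bin_edges) >= 2L,
            all(diff(bin_edges) > 0))
  k <- length(bin_edges) - 1L
  p <- dataset$records$power_mw
  idx <- findInterval(p, bin_edges, rightmost.closed = TRUE)
  outside <- which(idx < 1L | idx > k)
  if (length(outside) > 0L) {
    stop("power ", p[outside[1L]], " mW (row ", outside[1L],
         ") falls outside the supplied bins")
  }
  counts <- matrix(0L, nrow = k, ncol = length(OUTCOME_LEVELS),
                   dimnames = list(NULL, OUTCOME_LEVELS))
  if (length(p) > 0L) {
    tab <- table(factor(idx, levels = seq_len(k)),
                 factor(dataset$records$outcome, levels = OUTCOME_LEVELS))
    counts[] <- as.integer(tab)
  }
  n <- rowSums(counts)
  props <- counts / ifelse(n == 0L, NA_real_, n)
  colnames(props) <- paste0("prop_", OUTCOME_LEVELS)
  cbind(
    data.frame(bin_lo = bin_edges[-length(bin_edges)],
               bin_hi = bin_edges[-1L], n = n),
    as.data.frame(counts), as.data.frame(props)
  )
}

#' Proportion with exact binomial confidence interval
#'
#' Point estimate `successes / trials` with the exact two-sided
#' Clopper-Pearson interval (via [stats::binom.test()]).
#'
#' @param successes number of successes (0..trials).
#' @param trials number of trials (>= 1).
#' @param conf_level confidence level, default 0.95.
#' @return list with `estimate`, `lower`, `upper`, `successes`, `trials`,
#'   `conf_level`.
#' @export
proportion_estimate <- function(successes, trials, conf_level = 0.95) {
  if (!is.numeric(trials) || length(trials) != 1L || trials < 1) {
    stop("trials must be a single count >= 1")
  }
  stopifnot(is.numeric(successes), length(successes) == 1L,
            successes >= 0, successes <= trials)
  bt <- binom.test(successes, trials, conf.level = conf_level)
  list(estimate = unname(bt$estimate),
       lower = bt$conf.int[1L], upper = bt$conf.int[2L],
       successes = as.integer(successes), trials = as.integer(trials),
       conf_level = conf_level)
}
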