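#' Construct a growth table
#'
#' A growth table is the universal long-format container for plate-reader
#' growth data: one row per (time, well) observation with optical density
#' and categorical covariates.  It is an ordinary data frame with class
#' \code{growth_table} and an \code{is_log} attribute recording whether the
#' \code{od} column holds log2-transformed, baseline-normalized values.
#'
#' @param data data frame with at least columns \code{time} (hours,
#'   non-negative), \code{od} (optical density or log2-OD) and
#'   \code{replicate} (well identifier).  Optional columns \code{strain},
#'   \code{condition} and \code{batch} are treated as categorical covariates;
#'   any further columns are carried along untouched.
#' @param is_log logical; \code{TRUE} when \code{od} is log2-transformed and
#'   baseline-normalized.
#' @param validate run validity checks (default \code{TRUE}).
#' @return a \code{growth_table}.
#' @export
growth_table <- function(data, is_log = FALSE, validate = TRUE) {
  stopifnot(is.data.frame(data))
  required <- c("time", "od", "replicate")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("growth table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  for (cc in intersect(c("replicate", "strain", "condition", "batch"), names(data))) {
    data[[cc]] <- as.character(data[[cc]])
  }
  obj <- structure(data, class = c("growth_table", "data.frame"),
                   is_log = isTRUE(is_log))
  if (validate) validate_growth_table(obj)
  obj
}

#' @export
print.growth_table <- function(x, ...) {
  cat(sprintf("growth_table: %d observations, %d curve(s), %s scale\n",
              nrow(x), length(unique(curve_id(x))),
              if (is_log(x)) "log2 (baseline-normalized)" else "raw OD"))
  for (cc in intersect(c("strain", "condition", "batch"), names(x))) {
    cat(sprintf("  %s: %s\n", cc, paste(sort(unique(x[[cc]])), collapse = ", ")))
  }
  cat(sprintf("  time: %g to %g h (%d distinct points)\n",
              min(x$time), max(x$time), length(unique(x$time))))
  invisible(x)
}

#' @export
is_log <- function(table) UseMethod("is_log")

#' @export
is_log.growth_table <- function(table) isTRUE(attr(table, "is_log"))

#' Identifier of the growth curve each observation belongs to
#'
#' Replicate labels are typically reused across strains and conditions, so a
#' curve is keyed by the interaction of replicate with every categorical
#' covariate present.
#' @param table a growth table.
#' @return character vector, one id per row.
#' @keywords internal
curve_id <- function(table) {
  keys <- intersect(c("replicate", "strain", "condition", "batch"), names(table))
  do.call(paste, c(unname(as.list(table[keys])), sep = "\r"))
}

group_id <- function(table) {
  keys <- intersect(c("strain", "condition"), names(table))
  if (length(keys) == 0) return(rep("all", nrow(table)))
  do.call(paste, c(unname(as.list(table[keys])), sep = "\r"))
}

#' Validate a growth table
#'
#' Checks the structural invariants: numeric non-negative time, numeric od
#' with no missing values, and unique strictly ordered time points within
#' each curve.
#' @param table a growth table.
#' @return the table, invisibly; stops on violation.
#' @export
validate_growth_table <- function(table) {
  if (!is.numeric(table$time)) stop("'time' must be numeric", call. = FALSE)
  if (!is.numeric(table$od)) stop("'od' must be numeric", call. = FALSE)
  if (anyNA(table$time) || any(table$time < 0)) {
    stop("'time' must be non-negative with no missing values", call. = FALSE)
  }
  if (anyNA(table$od)) stop("'od' contains missing values", call. = FALSE)
  id <- curve_id(table)
  key <- paste(id, format(table$time, digits = 15))
  if (anyDuplicated(key)) {
    bad <- key[duplicated(key)][1]
    parts <- strsplit(bad, " ", fixed = TRUE)[[1]]
    stop(sprintf("duplicate (replicate, time) pair: replicate '%s' at time %s",
                 gsub("\r", "/", parts[1]), parts[2]), call. = FALSE)
  }
  invisible(table)
}

#' Read a growth table from delimited text
#'
#' @param path path to a CSV/TSV file with a header row.
#' @param column_map named character vector or list mapping growth-table
#'   fields to file column names, e.g.
#'   \code{c(time = "hours", od = "OD600", replicate = "well")}.  Fields not
#'   mentioned are taken from identically named file columns when present.
#' @param sep field separator; \code{","} by default, inferred as tab for
#'   \code{.tsv} files.
#' @return a \code{growth_table} with \code{is_log = FALSE}.  Unmapped file
#'   columns are preserved as extra covariate columns.
#' @export
read_growth_table <- function(path, column_map = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    column_map <- unlist(column_map)
    absent <- setdiff(unname(column_map), names(raw))
    if (length(absent) > 0) {
      stop("mapped column(s) not in file: ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
    for (field in names(column_map)) {
      names(raw)[names(raw) == column_map[[field]]] <- field
    }
  }
  for (num in c("time", "od")) {
    if (num %in% names(raw) && !is.numeric(raw[[num]])) {
      conv <- suppressWarnings(as.numeric(raw[[num]]))
      if (anyNA(conv)) {
        stop(sprintf("non-numeric '%s' value at row %d", num, which(is.na(conv))[1]),
             call. = FALSE)
      }
      raw[[num]] <- conv
    }
  }
  growth_table(raw, is_log = FALSE)
}

#' Write a growth table to CSV
#'
#' @param table a growth table.
#' @param path output file path.
#' @export
write_growth_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Log2-transform and baseline-normalize optical density
#'
#' OD values are log2-transformed, then the starting growth level of each
#' (strain, condition) group is estimated by a least-squares polynomial fit
#' to the pooled observations at the first \code{n_head} time points of the
#' group (all replicates pooled), and the polynomial's value at time zero is
#' subtracted from every log2-OD in the group, so that all groups start at
#' (approximately) zero.
#'
#' @param table a growth table on the raw OD scale (\code{is_log = FALSE}).
#' @param n_head number of leading distinct time points used for the
#'   baseline fit (default 10).
#' @param degree polynomial degree for the baseline regression (default 5).
#' @return the table with \code{od} replaced by normalized log2-OD and
#'   \code{is_log = TRUE}.
#' @export
log_baseline_normalize <- function(table, n_head = 10, degree = 5) {
  stopifnot(inherits(table, "growth_table"))
  if (is_log(table)) stop("table is already log-transformed", call. = FALSE)
  if (any(table$od <= 0)) {
    stop("od must be strictly positive for log2 transform", call. = FALSE)
  }
  lod <- log2(table$od)
  grp <- group_id(table)
  for (g in unique(grp)) {
    sel <- grp == g
    tg <- table$time[sel]
    head_times <- sort(unique(tg))[seq_len(min(n_head, length(unique(tg))))]
    if (length(head_times) < degree + 1) {
      stop(sprintf(
        "group '%s' has %d distinct head time points; need at least degree + 1 = %d",
        gsub("\r", "/", g), length(head_times), degree + 1), call. = FALSE)
    }
    in_head <- sel & table$time %in% head_times
    fit <- stats::lm(y ~ stats::poly(t, degree, raw = TRUE),
                     data = data.frame(t = table$time[in_head], y = lod[in_head]))
    baseline0 <- sum(stats::coef(fit) * c(1, rep(0, degree)))
    lod[sel] <- lod[sel] - baseline0
  }
  out <- table
  out$od <- lod
  attr(out, "is_log") <- TRUE
  out
}

#' Keep only time points on a coarser regular grid
#'
#' Retains observations whose time stamp is (within tolerance) an integer
#' multiple of \code{interval}.  A 48-h experiment sampled every 30 min
#' yields 12 time points per replicate at \code{interval = 4} and 8 at
#' \code{interval = 6} (time zero included, counting multiples up to but not
#' including the full span when the span itself is not retained by the
#' instrument grid -- i.e. multiples 0, 4, ..., 44 and 0, 6, ..., 42).
#'
#' @param table a growth table.
#' @param interval grid spacing in hours (> 0).
#' @param tol absolute tolerance on the grid match, hours.
#' @param keep_zero drop the time = 0 point when \code{FALSE}.
#' @return the subsampled growth table.
#' @export
subsample_timepoints <- function(table, interval, tol = 1e-6, keep_zero = TRUE) {
  stopifnot(inherits(table, "growth_table"), interval > 0)
  r <- table$time / interval
  keep <- abs(r - round(r)) < tol / interval
  if (!keep_zero) keep <- keep & table$time > tol
  if (length(unique(table$time[keep])) < 2) {
    stop("fewer than 2 time points fall on the requested grid; try a smaller interval",
         call. = FALSE)
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(table), is_log = is_log(table))
}

#' Random train/test split of growth observations
#'
#' Observations are partitioned at random without replacement within each
#' growth curve (replicate within strain/condition/batch), so that every
#' curve contributes both training and test points.
#'
#' @param table a growth table.
#' @param train_frac fraction of each curve's records assigned to training
#'   (default 0.8).
#' @param seed integer seed making the split reproducible.
#' @return list with elements \code{train} and \code{test}, both growth
#'   tables; their union is exactly the input.
#' @export
train_test_split <- function(table, train_frac = 0.8, seed = 1L) {
  stopifnot(inherits(table, "growth_table"),
            train_frac > 0, train_frac < 1)
  id <- curve_id(table)
  in_train <- logical(nrow(table))
  with_seed(seed, {
    for (cid in unique(id)) {
      rows <- which(id == cid)
      n_tr <- max(1L, min(length(rows) - 1L, round(train_frac * length(rows))))
      in_train[sample(rows, n_tr)] <- TRUE
    }
  })
  mk <- function(sel) {
    out <- table[sel, , drop = FALSE]
    rownames(out) <- NULL
    structure(out, class = class(table), is_log = is_log(table))
  }
  list(train = mk(in_train), test = mk(!in_train))
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
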