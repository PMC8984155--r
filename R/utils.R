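#' @importFrom utils read.delim write.table packageVersion combn
#' @importFrom stats quantile pchisq dhyper rnbinom rexp runif rbinom setNames
NULL

# deterministic per-stage child seeds derived from one pipeline seed
.childSeed <- function(seed, stage) {
  stages <- c("simulate", "detect", "dysreg", "enrich", "net", "risk")
  i <- match(stage, stages)
  if (is.na(i)) stop("unknown stage: ", stage)
  (as.integer(seed) + i * 10007L) %% .Machine$integer.max
}

.checkFraction <- function(x, name, open_left = FALSE, open_right = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  }
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!lo_ok || !hi_ok) stop(sprintf("'%s' out of range: %g", name, x), call. = FALSE)
  invisible(x)
}

# format one value for TSV output; Inf sentinels are written "+inf"/"-inf"
.fmtCell <- function(x) {
  if (is.numeric(x)) {
    out <- character(length(x))
    out[is.na(x)] <- "NA"
    out[!is.na(x) & x == Inf] <- "+inf"
    out[!is.na(x) & x == -Inf] <- "-inf"
    fin <- !is.na(x) & is.finite(x)
    out[fin] <- ifelse(x[fin] == round(x[fin]) & abs(x[fin]) < 1e15,
                       format(x[fin], scientific = FALSE, trim = TRUE),
                       sprintf("%.15g", x[fin]))
    out
  } else if (is.logical(x)) {
    ifelse(is.na(x), "NA", ifelse(x, "TRUE", "FALSE"))
  } else {
    out <- as.character(x)
    out[is.na(out)] <- "NA"
    out
  }
}

#' Write a result table as TSV with a commented unit header
#'
#' All result tables in the package are written through this function:
#' numeric columns at 15 significant digits (so a write/read round trip
#' preserves at least 12), infinite fold-change sentinels as
#' \code{"+inf"}/\code{"-inf"}, and optional per-column units as leading
#' \code{#} comment lines.
#'
#' @param df data.frame to write.
#' @param path output file path.
#' @param units optional named character vector mapping column names to a
#'   unit string, emitted as comment lines.
#' @return \code{path}, invisibly.
#' @export
writeResultTable <- function(df, path, units = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(units)) {
    for (nm in names(units)) {
      writeLines(sprintf("# column %s: %s", nm, units[[nm]]), con)
    }
  }
  cols <- lapply(df, .fmtCell)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0) {
    body <- do.call(paste, c(cols, sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a table written by \code{writeResultTable}
#'
#' Skips \code{#} comment lines and restores numeric columns, including the
#' \code{"+inf"}/\code{"-inf"} sentinels.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readResultTable <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   colClasses = "character", check.names = FALSE,
                   na.strings = character(0))
  for (j in seq_along(df)) {
    x <- df[[j]]
    miss <- x == "NA"
    y <- x
    y[y == "+inf"] <- "Inf"
    y[y == "-inf"] <- "-Inf"
    if (all(miss | x %in% c("TRUE", "FALSE"))) {
      df[[j]] <- as.logical(x)
      next
    }
    num <- suppressWarnings(as.numeric(y))
    if (!any(is.na(num) & !miss)) {
      num[miss] <- NA_real_
      df[[j]] <- num
    } else {
      x[miss] <- NA_character_
      df[[j]] <- x
    }
  }
  df
}
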