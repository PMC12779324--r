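#' Hypnogram: per-epoch vigilance-state labels
#'
#' Labels are drawn from `WAKE`, `NREM`, `REM`, `SWD` (seizure-masked epochs)
#' and `UNSCORED` on a fixed epoch grid. Epochs are indexed from 0 and cover
#' half-open intervals `[k * epoch_len_s, (k+1) * epoch_len_s)`.
#'
#' @param labels character vector of state labels.
#' @param epoch_len_s epoch length in seconds (default 5).
#' @return an object of class `"Hypnogram"`.
#' @export
hypnogram <- function(labels, epoch_len_s = 5) {
  h <- structure(list(labels = as.character(labels),
                      epoch_len_s = as.double(epoch_len_s)),
                 class = "Hypnogram")
  validate_hypnogram(h)
  h
}

#' Validate a Hypnogram
#' @param h a `Hypnogram`.
#' @return `h`, invisibly; errors on labels outside the state vocabulary or a
#'   non-positive epoch length.
#' @export
validate_hypnogram <- function(h) {
  stopifnot(inherits(h, "Hypnogram"))
  if (!is.finite(h$epoch_len_s) || h$epoch_len_s <= 0)
    stop("epoch_len_s must be > 0")
  bad <- setdiff(unique(h$labels), STATE_LEVELS)
  if (length(bad)) stop("unknown hypnogram label(s): ", paste(bad, collapse = ", "))
  invisible(h)
}

#' @export
print.Hypnogram <- function(x, ...) {
  cat(sprintf("Hypnogram: %d epochs x %.3g s (%.1f min)\n",
              n_epochs(x), x$epoch_len_s, n_epochs(x) * x$epoch_len_s / 60))
  tab <- table(factor(x$labels, levels = STATE_LEVELS))
  tab <- tab[tab > 0]
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Number of epochs in a hypnogram
#' @param h a `Hypnogram`.
#' @return integer epoch count.
#' @export
n_epochs <- function(h) length(h$labels)

#' Start times (seconds) of each epoch
#' @param h a `Hypnogram`.
#' @return numeric vector of epoch start times from recording start.
#' @export
epoch_starts <- function(h) (seq_len(n_epochs(h)) - 1) * h$epoch_len_s
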