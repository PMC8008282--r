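# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_oe <- function(..., class) {
  stop(structure(
    class = c(class, "oculoeffort_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_oe(name, " must be a finite numeric scalar", class = "oe_validation_error")
  if (positive && x <= 0)
    stop_oe(name, " must be > 0", class = "oe_validation_error")
  invisible(x)
}

# Maximal runs of TRUE in a logical vector (NA counts as FALSE).
# Returns a two-column matrix of start/end indices.
true_runs <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Centered moving sum with zero padding outside the signal, length preserved.
padded_moving_sum <- function(x, w) {
  n <- length(x)
  h <- (w - 1L) %/% 2L
  xp <- c(rep(0, h), x, rep(0, h))
  cs <- cumsum(xp)
  # window around i covers xp[i .. i + w - 1]
  cs_hi <- cs[seq_len(n) + w - 1L]
  cs_lo <- c(0, cs)[seq_len(n)]
  cs_hi - cs_lo
}

# Moving average ignoring NAs; NA where the window holds no data.
moving_average_na <- function(x, w) {
  ok <- !is.na(x)
  s <- padded_moving_sum(ifelse(ok, x, 0), w)
  cnt <- padded_moving_sum(as.numeric(ok), w)
  out <- s / cnt
  out[cnt == 0] <- NA_real_
  out
}

key_pt <- function(participant, trial) paste(participant, trial, sep = ":")
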