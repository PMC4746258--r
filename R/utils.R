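# Internal helpers shared across modules.

# abort with a classed condition so callers/tests can match on error class
rc_abort <- function(msg, class) {
  stop(structure(
    class = c(class, "radialcells_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

rc_warn <- function(msg, class = "radialcells_warning") {
  warning(structure(
    class = c(class, "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# pixel (row, col) positions of a label in a label map, as a two-column matrix
label_pixels <- function(labels, id) {
  which(labels == id, arr.ind = TRUE)
}

# relabel positive labels to consecutive 1..K preserving numeric order;
# returns the relabelled map
relabel_consecutive <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0L) return(labels)
  lut <- integer(max(ids))
  lut[ids] <- seq_along(ids)
  out <- labels
  pos <- labels > 0
  out[pos] <- lut[labels[pos]]
  out
}

stopifnot_matrix <- function(x, arg = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    rc_abort(sprintf("`%s` must be a numeric matrix", arg), "rc_type_error")
  invisible(x)
}
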