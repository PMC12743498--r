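#' Binary edge-trace map
#'
#' A binary grid marking traced pixels (1 = traced). One map corresponds to
#' one drawing: an observer's trace of one image in one condition. The
#' noise-free trace of an image serves as that observer's individual ground
#' truth (the SDT "signal"); the same observer's noisy-condition traces are
#' the "responses" scored against it.
#'
#' @param mask logical or 0/1 numeric matrix.
#' @param observer_id,image_id,condition optional identifiers carried as
#'   attributes.
#' @return An object of class `trace_map` (integer 0/1 matrix).
#' @export
trace_map <- function(mask, observer_id = NA, image_id = NA, condition = NA) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix")
  if (is.logical(mask)) mask <- mask * 1L
  if (!is.numeric(mask) || anyNA(mask) || !all(mask %in% c(0, 1)))
    stop("`mask` must be strictly binary (0/1 or logical)")
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  structure(m,
            observer_id = observer_id,
            image_id = image_id,
            condition = condition,
            class = c("trace_map", "matrix", "array"))
}

#' @export
print.trace_map <- function(x, ...) {
  cat(sprintf("<trace_map> %dx%d px, %d traced (%.2f%%)%s\n",
              nrow(x), ncol(x), sum(x), 100 * mean(x),
              if (!is.na(attr(x, "observer_id")))
                sprintf(" [obs %s, img %s, %s]",
                        attr(x, "observer_id"), attr(x, "image_id"),
                        attr(x, "condition")) else ""))
  invisible(x)
}

is_trace_map <- function(x) inherits(x, "trace_map")

as_binary_matrix <- function(x) {
  m <- unclass(x)
  attributes(m) <- list(dim = dim(x))
  m > 0
}
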