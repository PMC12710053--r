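# Internal helpers shared across modules.

# Shift a matrix by (dr, dc), padding with `fill`.  Used by the vectorized
# thinning and neighbourhood code; avoids building index matrices per call.
shift_mat <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(rs) < 1L || length(cs) < 1L) return(out)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Round half away from zero: deterministic across platforms, unlike round()
# which rounds half to even.
round_half_up <- function(x) floor(x + 0.5)

# Validate a half-open pixel box (x_min, y_min, x_max, y_max), 0-based.
check_box <- function(box, rows = NULL, cols = NULL) {
  stopifnot(length(box) == 4, all(is.finite(box)))
  if (box[1] >= box[3] || box[2] >= box[4])
    stop("degenerate box: ", paste(box, collapse = ","))
  if (!is.null(rows)) {
    if (box[1] < 0 || box[2] < 0 || box[3] > cols || box[4] > rows)
      stop("box outside image bounds: ", paste(box, collapse = ","))
  }
  invisible(box)
}

# Logical matrix of the box interior (half-open, 0-based coords).
box_to_mask <- function(box, rows, cols) {
  m <- matrix(FALSE, rows, cols)
  m[(box[2] + 1):box[4], (box[1] + 1):box[3]] <- TRUE
  m
}

# Tight half-open bounding box of a logical mask, 0-based (x_min, y_min,
# x_max, y_max); NULL for an empty mask.
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  c(min(idx[, 2]) - 1L, min(idx[, 1]) - 1L, max(idx[, 2]), max(idx[, 1]))
}

# Serialize a character vector of flags to the CSV field representation.
flags_to_string <- function(flags) {
  if (length(flags) == 0L) "" else paste(sort(unique(flags)), collapse = ";")
}

string_to_flags <- function(s) {
  if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ";", fixed = TRUE)[[1]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
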