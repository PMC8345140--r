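# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All package randomness flows through this
# (single stated generator: R's default Mersenne-Twister).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single value in [0, 1]", name), call. = FALSE)
  invisible(x)
}

# clip numeric array into [lo, hi]
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_binary_matrix <- function(m) {
  is.matrix(m) && all(m %in% c(0, 1, FALSE, TRUE))
}

as_binary <- function(m) {
  storage.mode(m) <- "integer"
  m
}

# 8-connected component labelling of a logical/0-1 matrix by iterative label
# propagation (each foreground pixel starts with a unique id and repeatedly
# takes the minimum id over its 3x3 neighbourhood until a fixed point).
# EBImage::bwlabel is 4-connected, which merges fewer diagonal contacts than
# the 8-connectivity used throughout this package, hence the own labeller.
label_components <- function(mask) {
  mask <- mask > 0
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  n_fg <- sum(mask)
  if (n_fg == 0L) return(lab)
  lab[mask] <- seq_len(n_fg)
  shift_min <- function(m) {
    big <- matrix(Inf, H + 2L, W + 2L)
    big[2:(H + 1L), 2:(W + 1L)] <- ifelse(mask, lab, Inf)
    out <- matrix(Inf, H, W)
    for (dr in -1:1) for (dc in -1:1) {
      out <- pmin(out, big[(2:(H + 1L)) + dr, (2:(W + 1L)) + dc])
    }
    out
  }
  repeat {
    nb <- shift_min(mask)
    new <- ifelse(mask, pmin(lab, nb), 0)
    if (all(new == lab)) break
    lab <- new
  }
  # relabel 1..K in first-pixel order
  ids <- unique(lab[lab > 0])
  lab2 <- matrix(0L, H, W)
  lab2[lab > 0] <- match(lab[lab > 0], ids)
  lab2
}

# consecutive relabelling of an instance map, preserving label order
relabel_consecutive <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0L) {
    storage.mode(labels) <- "integer"
    return(labels)
  }
  out <- matrix(0L, nrow(labels), ncol(labels))
  out[labels > 0] <- match(labels[labels > 0], ids)
  out
}
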