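# Memoised within-deme results on the integer inoculum lattice.
#
# The growth phase is deterministic in (inoculum, world), so final sizes are
# cached per world in k-dimensional arrays indexed by inoculum counts
# (offset by 1).  The cache lives in the world's private environment and is
# shared by the expectation map, the Price decomposition, the Monte Carlo
# ensemble and all phase-plane machinery.

# linear index of 1-based k-dim indices in an array of dimension `dims`
.lin_idx <- function(indmat, dims) {
  mult <- cumprod(c(1, dims[-length(dims)]))
  as.vector((indmat - 1) %*% mult) + 1
}

# grow the cache arrays so that dims >= need componentwise
.ensure_dims <- function(world, need) {
  k <- .n_strains(world)
  cache <- world$cache
  if (is.null(cache$dims)) {
    cache$dims <- as.integer(need)
    cache$finals <- lapply(seq_len(k), function(i) array(NA_real_, dim = need))
    cache$computed <- array(FALSE, dim = need)
    cache$n_solves <- 0L
  } else if (any(need > cache$dims)) {
    newdims <- pmax(as.integer(need), cache$dims)
    old_idx <- lapply(cache$dims, seq_len)
    grow <- function(old, fill) {
      arr <- array(fill, dim = newdims)
      do.call(`[<-`, c(list(arr), old_idx, list(old)))
    }
    cache$finals <- lapply(cache$finals, grow, fill = NA_real_)
    cache$computed <- grow(cache$computed, fill = FALSE)
    cache$dims <- newdims
  }
  cache
}

# compute and store final sizes for the given 1-based index matrix
.fill_points <- function(world, cache, ind) {
  if (!nrow(ind)) return(invisible())
  nmat <- ind - 1L
  finals <- .deme_finals(nmat, world)
  lin <- .lin_idx(ind, cache$dims)
  for (i in seq_len(ncol(ind))) cache$finals[[i]][lin] <- finals[, i]
  cache$computed[lin] <- TRUE
  cache$n_solves <- cache$n_solves + nrow(ind)
  invisible()
}

# Ensure final sizes are cached for every inoculum n with 0 <= n_i <=
# upper_i.  Returns list of k arrays of dim upper+1 (the requested block).
.ensure_lattice <- function(world, upper, max_lattice = 4e6) {
  k <- .n_strains(world)
  stopifnot(length(upper) == k)
  need <- as.integer(upper) + 1L
  if (prod(as.numeric(need)) > max_lattice)
    stop("inoculum lattice of ", format(prod(as.numeric(need)), big.mark = ","),
         " points exceeds the cap (", format(max_lattice, big.mark = ","),
         "); use a coarser truncation mass tolerance or smaller means")
  cache <- .ensure_dims(world, need)

  block_idx <- lapply(need, seq_len)
  comp_block <- do.call(`[`, c(list(cache$computed), block_idx, list(drop = FALSE)))
  miss <- which(!comp_block)
  if (length(miss)) .fill_points(world, cache, arrayInd(miss, .dim = need))

  lapply(seq_len(k), function(i)
    do.call(`[`, c(list(cache$finals[[i]]), block_idx, list(drop = FALSE))))
}

# Cached point queries: final sizes for an arbitrary matrix of integer
# inocula (one per row), computing only entries not previously seen.
.deme_finals_cached <- function(nmat, world) {
  if (world$interaction$kind == "base") return(.base_finals(nmat, world)$finals)
  k <- ncol(nmat)
  need <- apply(nmat, 2, max) + 1L
  cache <- .ensure_dims(world, need)
  ind <- nmat + 1L
  lin <- .lin_idx(ind, cache$dims)
  miss <- !cache$computed[lin]
  if (any(miss)) .fill_points(world, cache, ind[miss, , drop = FALSE])
  out <- matrix(0, nrow(nmat), k)
  for (i in seq_len(k)) out[, i] <- cache$finals[[i]][lin]
  out
}
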