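#' Construct a parcellation book with leakage model
#'
#' Builds the anatomy-side scaffolding the pipeline needs: a fine parcellation
#' with a 2-to-1 collapse onto a coarse parcellation, functional system labels
#' (the seven resting-state systems: Visual, SM, DAN, VAN, Lim, FPN, DMN),
#' functional subdivisions of the visual system, per-parcel source
#' reconstruction fidelity, and a row-stochastic zero-lag leakage (mixing)
#' matrix built from a spatial kernel on a 1-D circular parcel layout.
#'
#' Fidelity is sampled first and then used as the diagonal (self-weight) of the
#' corresponding mixing row, so the self-weight share of each row *is* the
#' parcel's fidelity. A configurable fraction of parcels is given fidelity
#' below the usual 0.165 exclusion threshold to emulate poorly reconstructed
#' cortex.
#'
#' @param n_fine Number of fine parcels (even, >= 4). Default 400.
#' @param seed Integer seed; the book is deterministic given the seed.
#' @param locality Length scale of the Gaussian leakage kernel on the unit
#'   circle (parcel spacing is `1/n_fine`). `0` gives identity mixing.
#' @param fidelity_range Range from which ordinary parcels' fidelity is drawn.
#' @param frac_low_fidelity Fraction of parcels whose fidelity is drawn below
#'   0.165 (default 0.065, i.e. 6.5% of parcels).
#' @return An object of class `parcel_book`: list with `parcel_ids`,
#'   `coarse_map` (fine -> coarse index), `system`, `visual_subdivision`,
#'   `fidelity`, `mixing` (n_fine x n_fine), and `position` (layout coordinate).
#' @export
make_parcel_book <- function(n_fine = 400L, seed = 1L, locality = 0.008,
                             fidelity_range = c(0.85, 0.98),
                             frac_low_fidelity = 0.065) {
  if (n_fine < 4 || n_fine %% 2 != 0) {
    stop("n_fine must be an even integer >= 4", call. = FALSE)
  }
  if (locality < 0) stop("locality must be >= 0", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(child_seed(seed, 11L))

  p <- as.integer(n_fine)
  pos <- (seq_len(p) - 1) / p

  # system labels in contiguous even-sized blocks so that coarse pairs
  # (2k-1, 2k) never straddle a system boundary
  sys_levels <- c("Visual", "SM", "DAN", "VAN", "Lim", "FPN", "DMN")
  prop <- c(Visual = 0.30, SM = 0.10, DAN = 0.14, VAN = 0.10,
            Lim = 0.06, FPN = 0.16, DMN = 0.14)
  npair <- p %/% 2L
  target <- prop * npair
  alloc <- floor(target)
  rem <- npair - sum(alloc)
  if (rem > 0) {
    top <- order(target - alloc, decreasing = TRUE)[seq_len(rem)]
    alloc[top] <- alloc[top] + 1L
  }
  sizes <- 2L * alloc
  system <- factor(rep(sys_levels, times = sizes), levels = sys_levels)

  # visual subdivisions: contiguous even blocks inside the Visual block,
  # allocated pair-wise so coarse parcels never straddle a subdivision;
  # the task-relevant subdivisions (Early, LOC, V4V8, Dorsal) are filled first
  sub_levels <- c("Early", "LOC", "V4V8", "Ventral", "Dorsal")
  nv <- sizes[1]
  npairs <- nv %/% 2L
  fill_order <- c(1L, 2L, 3L, 5L, 4L)  # Ventral last
  pair_counts <- integer(5)
  pair_counts[fill_order] <- npairs %/% 5L +
    (seq_len(5) <= npairs %% 5L)
  ssz <- 2L * pair_counts
  subdivision <- factor(rep("none", p), levels = c(sub_levels, "none"))
  subdivision[seq_len(nv)] <- rep(sub_levels, times = ssz)

  # fidelity: most parcels high, a configurable fraction below 0.165
  fidelity <- stats::runif(p, fidelity_range[1], fidelity_range[2])
  n_low <- round(frac_low_fidelity * p)
  if (n_low > 0) {
    low <- sample.int(p, n_low)
    fidelity[low] <- stats::runif(n_low, 0.05, 0.164)
  }

  mixing <- .make_mixing(pos, fidelity, locality)

  structure(list(
    n_fine = p,
    parcel_ids = sprintf("parcel_%03d", seq_len(p)),
    coarse_map = as.integer((seq_len(p) + 1L) %/% 2L),
    system = system,
    visual_subdivision = subdivision,
    fidelity = fidelity,
    mixing = mixing,
    position = pos,
    locality = locality,
    seed = as.integer(seed)
  ), class = "parcel_book")
}

# Gaussian kernel on the circle; diagonal = fidelity, off-diagonal mass scaled
# to (1 - fidelity) so each row sums to 1. Kernel support is symmetric.
.make_mixing <- function(pos, fidelity, locality) {
  p <- length(pos)
  if (locality <= 0) {
    m <- diag(p)
    return(m)
  }
  d <- abs(outer(pos, pos, "-"))
  d <- pmin(d, 1 - d)
  k <- exp(-d^2 / (2 * locality^2))
  diag(k) <- 0
  k[k < 1e-10] <- 0   # keeps the support exactly symmetric across rows
  rs <- rowSums(k)
  m <- diag(fidelity)
  ok <- rs > 1e-12
  m[ok, ] <- m[ok, , drop = FALSE] +
    (1 - fidelity[ok]) * k[ok, , drop = FALSE] / rs[ok]
  # rows with no kernel neighbourhood keep all mass on the diagonal
  if (any(!ok)) diag(m)[!ok] <- 1
  m
}

#' @export
print.parcel_book <- function(x, ...) {
  cat("parcel_book:", x$n_fine, "fine parcels ->", max(x$coarse_map),
      "coarse parcels\n")
  cat("  systems:", paste(sprintf("%s=%d", levels(x$system),
                                  tabulate(x$system)), collapse = " "), "\n")
  cat(sprintf("  fidelity: median %.3f, %d parcel(s) below 0.165\n",
              stats::median(x$fidelity), sum(x$fidelity < 0.165)))
  cat(sprintf("  leakage locality: %g\n", x$locality))
  invisible(x)
}

#' Number of coarse parcels of a book
#' @param book A `parcel_book`.
#' @return Integer count of coarse parcels.
#' @export
n_coarse <- function(book) max(book$coarse_map)

#' Collapse the mixing matrix to the coarse parcellation
#'
#' Coarse mixing is the average of the fine-block rows/columns, re-normalized
#' to row-stochastic form; coarse fidelity is the self-weight of each row.
#'
#' @param book A `parcel_book`.
#' @return List with `mixing` (coarse matrix), `fidelity`, `system`,
#'   `visual_subdivision` (label of the first member of each coarse parcel).
#' @export
coarse_book <- function(book) {
  s <- .collapse_operator(book)
  m <- s %*% book$mixing %*% t(s)
  m <- m / rowSums(m)
  first <- match(seq_len(n_coarse(book)), book$coarse_map)
  list(mixing = m,
       fidelity = diag(m),
       sampled_fidelity = as.vector(s %*% book$fidelity),
       system = book$system[first],
       visual_subdivision = book$visual_subdivision[first])
}

# n_coarse x n_fine averaging operator (rows sum to 1)
.collapse_operator <- function(book) {
  nc <- n_coarse(book)
  s <- matrix(0, nc, book$n_fine)
  s[cbind(book$coarse_map, seq_len(book$n_fine))] <- 1
  s / rowSums(s)
}

# save/restore the global RNG state so constructors don't perturb user code
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
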