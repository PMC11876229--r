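# Permutation-set construction and gapped 3x3 puzzle sampling: the data
# layer of the jigsaw pretext task. A permutation p of 1..n is read as
# "grid slot i (row-major, top-left origin) receives the patch originally
# at position p[i]"; that one convention is used everywhere and is pinned
# by the apply/invert round-trip tests.

#' Hamming distance between two permutations
#'
#' Number of positions at which two permutations of the same length
#' disagree. Between a permutation and the identity this counts non-fixed
#' points, so derangements sit at the maximal distance (9 of 9 for the
#' 3x3 grid).
#'
#' @param p,q Integer vectors, each a permutation of `1:length(p)`.
#' @return Integer in `0:length(p)`.
#' @export
hamming_distance <- function(p, q) {
  check_permutation(p)
  check_permutation(q)
  if (length(p) != length(q))
    stop("permutations must have equal length", call. = FALSE)
  sum(p != q)
}

check_permutation <- function(p) {
  if (!is.numeric(p) || anyNA(p) || !identical(sort(as.integer(p)), seq_along(p)))
    stop("not a valid permutation of 1..n", call. = FALSE)
  invisible(TRUE)
}

#' Invert a permutation
#' @param p Integer vector, a permutation of `1:length(p)`.
#' @return The inverse permutation.
#' @export
invert_permutation <- function(p) {
  check_permutation(p)
  order(p)
}

is_derangement <- function(p) all(p != seq_along(p))

sample_derangement <- function(n) {
  repeat {
    p <- sample.int(n)
    if (all(p != seq_len(n))) return(p)
  }
}

#' Build the maximal-Hamming permutation set for the pretext task
#'
#' Constructs the label space of the puzzle task: the identity permutation
#' plus `n_extra` derangements (permutations at maximal Hamming distance
#' from the identity), chosen from a seeded pool of distinct random
#' derangements by greedy max-min dispersion: each step adds the candidate
#' whose minimum Hamming distance to the already-selected set is largest,
#' ties broken by the larger mean distance, then by sampling order.
#'
#' @param n_extra Number of non-identity permutations (30 for the standard
#'   31-class set).
#' @param pool_size Number of distinct candidate derangements to sample.
#' @param seed Integer seed driving both pool sampling and selection.
#' @param n_items Grid size squared (9 for the 3x3 grid; 4 only for toy
#'   oracle checks).
#' @param pool Optional explicit candidate pool (matrix, one permutation
#'   per row) overriding the sampled pool; rows must be derangements.
#' @return An object of class `permutation_set`: list with `perms` (matrix,
#'   one permutation per row, row 1 = identity; class label of row i is
#'   `i - 1`), `seed`, and `mean_pairwise_hamming`.
#' @export
generate_permutation_set <- function(n_extra = 30L, pool_size = 1000L,
                                     seed = 1L, n_items = 9L, pool = NULL) {
  n_extra <- as.integer(n_extra)
  if (n_extra < 1L) stop("n_extra must be >= 1", call. = FALSE)
  withr::local_seed(seed)
  if (is.null(pool)) {
    if (pool_size < n_extra)
      stop("pool_size must be >= n_extra", call. = FALSE)
    seen <- new.env(hash = TRUE, parent = emptyenv())
    pool <- matrix(0L, pool_size, n_items)
    i <- 0L
    while (i < pool_size) {
      p <- sample_derangement(n_items)
      k <- paste(p, collapse = ",")
      if (is.null(seen[[k]])) {
        assign(k, TRUE, envir = seen)
        i <- i + 1L
        pool[i, ] <- p
      }
    }
  } else {
    pool <- matrix(as.integer(pool), nrow = nrow(pool))
    apply(pool, 1, check_permutation)
    if (!all(apply(pool, 1, is_derangement)))
      stop("explicit pool must contain only derangements", call. = FALSE)
    if (nrow(pool) < n_extra)
      stop("pool exhausted before n_extra selected", call. = FALSE)
  }
  identity <- seq_len(n_items)
  sel <- matrix(identity, 1L, n_items)
  # running min/sum of distances from each candidate to the selected set
  dist_to <- function(p) rowSums(pool != matrix(p, nrow(pool), n_items, byrow = TRUE))
  mind <- dist_to(identity)
  sumd <- mind
  taken <- logical(nrow(pool))
  for (j in seq_len(n_extra)) {
    mn <- ifelse(taken, -1L, mind)
    best <- max(mn)
    cand <- which(mn == best)
    if (length(cand) > 1L) {
      mu <- sumd[cand] / nrow(sel)
      cand <- cand[mu == max(mu)]
    }
    pick <- cand[1L]  # earliest in sampling order
    taken[pick] <- TRUE
    sel <- rbind(sel, pool[pick, ])
    d <- dist_to(pool[pick, ])
    mind <- pmin(mind, d)
    sumd <- sumd + d
  }
  rownames(sel) <- NULL
  set <- structure(list(perms = sel, seed = as.integer(seed),
                        mean_pairwise_hamming = NA_real_),
                   class = "permutation_set")
  set$mean_pairwise_hamming <- mean_pairwise_hamming(set)
  set
}

#' Mean pairwise Hamming distance of a permutation set
#'
#' Arithmetic mean of [hamming_distance()] over all unordered pairs of the
#' set (465 pairs for the 31-element set).
#'
#' @param set A `permutation_set` (or a plain matrix of permutations, one
#'   per row).
#' @return A single number.
#' @export
mean_pairwise_hamming <- function(set) {
  perms <- if (inherits(set, "permutation_set")) set$perms else set
  n <- nrow(perms)
  if (n < 2L) stop("need at least two permutations", call. = FALSE)
  tot <- 0
  for (i in seq_len(n - 1L))
    for (j in seq(i + 1L, n))
      tot <- tot + sum(perms[i, ] != perms[j, ])
  tot / (n * (n - 1L) / 2)
}

#' @export
print.permutation_set <- function(x, ...) {
  cat(sprintf("permutation set: %d classes over %d slots, mean pairwise Hamming %.3f (seed %d)\n",
              nrow(x$perms), ncol(x$perms), x$mean_pairwise_hamming, x$seed))
  invisible(x)
}

#' Serialize / read a permutation set
#'
#' CSV with one row per permutation (9 integer columns, row order = class
#' label order) and a JSON sidecar carrying the seed and the mean pairwise
#' Hamming distance.
#'
#' @param set A `permutation_set`.
#' @param csv_path Output CSV path; the sidecar is written next to it with
#'   extension `.json`.
#' @return `csv_path`, invisibly.
#' @export
write_permutation_set <- function(set, csv_path) {
  stopifnot(inherits(set, "permutation_set"))
  utils::write.table(set$perms, csv_path, sep = ",", row.names = FALSE,
                     col.names = paste0("slot", seq_len(ncol(set$perms))))
  side <- sub("\\.csv$", ".json", csv_path)
  if (identical(side, csv_path)) side <- paste0(csv_path, ".json")
  jsonlite::write_json(list(seed = set$seed,
                            mean_pairwise_hamming = set$mean_pairwise_hamming),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' @rdname write_permutation_set
#' @export
read_permutation_set <- function(csv_path) {
  perms <- as.matrix(utils::read.csv(csv_path))
  storage.mode(perms) <- "integer"
  dimnames(perms) <- NULL
  side <- sub("\\.csv$", ".json", csv_path)
  if (identical(side, csv_path)) side <- paste0(csv_path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list(seed = NA)
  structure(list(perms = perms, seed = meta$seed,
                 mean_pairwise_hamming = mean_pairwise_hamming(perms)),
            class = "permutation_set")
}

#' Geometry of the gapped puzzle grid
#'
#' The image is tiled into a 3x3 grid of `cell_size` cells anchored at
#' `(row * cell_size, col * cell_size)` (0-based); within each cell a
#' `patch_size` window is drawn with an independent uniform jitter of
#' `0..jitter_range` pixels per axis, which realizes the random gaps
#' between patches. With the defaults (512 = 3 * 170 + 2) the two leftover
#' pixel rows/columns at the right and bottom are discarded.
#'
#' @param image_size Side length of the (square) input crop.
#' @param grid_n Cells per side (3; 2 exists only for toy oracle checks).
#' @param cell_size Cell side in pixels.
#' @param patch_size Extracted patch side in pixels.
#' @param jitter_range Maximum jitter per axis, inclusive.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(image_size = 512L, grid_n = 3L, cell_size = 170L,
                      patch_size = 150L, jitter_range = 20L) {
  image_size <- as.integer(image_size); grid_n <- as.integer(grid_n)
  cell_size <- as.integer(cell_size); patch_size <- as.integer(patch_size)
  jitter_range <- as.integer(jitter_range)
  if (grid_n * cell_size > image_size)
    stop("grid does not fit: grid_n * cell_size > image_size", call. = FALSE)
  if (patch_size + jitter_range > cell_size)
    stop("patch_size + jitter_range must be <= cell_size", call. = FALSE)
  structure(list(image_size = image_size, grid_n = grid_n,
                 cell_size = cell_size, patch_size = patch_size,
                 jitter_range = jitter_range),
            class = "grid_spec")
}

standardize_patch <- function(p) {
  s <- stats::sd(as.vector(p))
  if (!is.finite(s) || s == 0) return(p * 0)
  (p - mean(p)) / s
}

#' Sample a gapped jigsaw puzzle from a crop
#'
#' Tiles the image into the grid's cells, draws one jittered patch window
#' per cell (the random gaps), reorders the patches by the permutation with
#' class label `perm_label`, and standardizes each patch to zero mean and
#' unit variance independently (constant patches become all-zero), so the
#' puzzle cannot be solved from absolute brightness alone.
#'
#' @param image Numeric matrix, exactly `grid$image_size` on each side.
#' @param perm_label Integer class label in `0:(nrow(permset$perms) - 1)`.
#' @param permset A `permutation_set`.
#' @param grid A `grid_spec`.
#' @param seed Optional integer; when given, jitter is drawn under this
#'   seed (leaving the caller's RNG untouched), otherwise from the current
#'   RNG stream.
#' @param standardize Standardize patches (default TRUE).
#' @param source_image_id Optional identifier of the source image, carried
#'   through to the returned sample.
#' @return An object of class `puzzle_sample`: list with `patches` (list of
#'   `grid_n^2` matrices in slot order), `label`, `jitter` (matrix of the
#'   drawn offsets in original cell order), and `source_image_id`.
#' @export
sample_puzzle <- function(image, perm_label, permset, grid = grid_spec(),
                          seed = NULL, standardize = TRUE,
                          source_image_id = NA_character_) {
  stopifnot(inherits(permset, "permutation_set"), inherits(grid, "grid_spec"))
  if (nrow(image) != grid$image_size || ncol(image) != grid$image_size)
    stop("image must be exactly ", grid$image_size, "x", grid$image_size,
         call. = FALSE)
  n_class <- nrow(permset$perms)
  if (perm_label < 0L || perm_label >= n_class)
    stop("perm_label out of range 0..", n_class - 1L, call. = FALSE)
  if (ncol(permset$perms) != grid$grid_n^2)
    stop("permutation length does not match grid", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)
  g <- grid$grid_n
  jit <- matrix(sample.int(grid$jitter_range + 1L, 2L * g * g,
                           replace = TRUE) - 1L, ncol = 2L)
  patches <- vector("list", g * g)
  idx <- 1L
  for (row in 0:(g - 1L)) {
    for (col in 0:(g - 1L)) {
      r0 <- row * grid$cell_size + jit[idx, 1L]
      c0 <- col * grid$cell_size + jit[idx, 2L]
      p <- image[(r0 + 1L):(r0 + grid$patch_size),
                 (c0 + 1L):(c0 + grid$patch_size)]
      patches[[idx]] <- if (standardize) standardize_patch(p) else p
      idx <- idx + 1L
    }
  }
  perm <- permset$perms[perm_label + 1L, ]
  structure(list(patches = patches[perm], label = as.integer(perm_label),
                 jitter = jit, source_image_id = source_image_id),
            class = "puzzle_sample")
}

#' Enumerate all permutations of 1..n
#'
#' Plain recursive-expansion enumeration, used for exhaustive oracles on
#' the toy 2x2 grid and to enumerate the full 9! ordering space.
#'
#' @param n Number of items (kept small; 9 gives 362880 rows).
#' @return Integer matrix with `factorial(n)` rows, one permutation per row.
#' @export
enumerate_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- enumerate_permutations(n - 1L)
  out <- matrix(0L, factorial(n), n)
  m <- nrow(sub)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * m + 1L):(i * m)
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], m, n - 1L)
  }
  out
}
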