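# shared low-level helpers: connected components, matrix shifts, seeded RNG

# Shift a matrix by (dr, dc) with replicated borders; out[i,j] = m[i+dr, j+dc].
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

#' Label connected components of a binary mask
#'
#' 8-connected labeling built from EBImage's 4-connected [EBImage::bwlabel()]
#' pass followed by union-find merging of labels that touch diagonally.
#' Label ids are compacted to 1..k in order of first appearance (column-major),
#' so the result is deterministic.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8; thin diagonal structures such as
#'   tendrils form single components only under 8-connectivity).
#' @return integer matrix of component labels, 0 for background.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  L <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  storage.mode(L) <- "integer"
  if (connectivity == 4) return(L)
  nlab <- max(L)
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  merge_pairs <- function(a, b) {
    sel <- a > 0L & b > 0L & a != b
    if (!any(sel)) return(invisible())
    pr <- unique(cbind(a[sel], b[sel]))
    for (k in seq_len(nrow(pr))) {
      ra <- find(pr[k, 1]); rb <- find(pr[k, 2])
      if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    }
  }
  nr <- nrow(L); nc <- ncol(L)
  merge_pairs(L[-nr, -nc, drop = FALSE], L[-1, -1, drop = FALSE])   # \ diagonal
  merge_pairs(L[-nr, -1, drop = FALSE], L[-1, -nc, drop = FALSE])   # / diagonal
  root <- vapply(seq_len(nlab), find, integer(1))
  fg <- L > 0L
  rooted <- root[L[fg]]
  new_id <- match(rooted, unique(rooted))
  L[fg] <- new_id
  L
}

# Pixel counts per component label (ignores background 0).
component_sizes <- function(labels) {
  n <- max(labels)
  if (n == 0L) return(integer(0))
  tabulate(labels[labels > 0L], nbins = n)
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Tiny FNV-1a hash of a config list, for table header provenance comments.
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
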