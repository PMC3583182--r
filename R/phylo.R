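## Distance phylogenetics: p-distances under pairwise deletion, Poisson
## correction d = -ln(1 - p), Saitou-Nei neighbor-joining, bootstrap
## supports, and simple majority consensus sequences.  Trees are ape
## "phylo" objects throughout.

#' Coerce to a protein multiple alignment
#'
#' @param x A named character vector of equal-length rows, or a
#'   [Biostrings::AAStringSet].
#' @return A named uppercase character vector (the alignment rows).
#' @export
as_alignment <- function(x) {
  if (is(x, "XStringSet")) x <- setNames(as.character(x), names(x))
  stopifnot(is.character(x), length(x) >= 2L, !is.null(names(x)),
            all(nzchar(names(x))), !anyDuplicated(names(x)))
  if (length(unique(nchar(x))) != 1L) {
    stop("alignment rows must all have the same length")
  }
  toupper(x)
}

.aln_matrix <- function(aln) {
  do.call(rbind, strsplit(unname(aln), ""))
}

#' Proportion of differing sites between two alignment rows
#'
#' Sites where either row holds a gap (`-`) or missing residue (`X`) are
#' excluded (pairwise deletion).  Returns `NA` when no comparable sites
#' remain.
#'
#' @param aln An alignment (see [as_alignment()]).
#' @param i,j Row indices or names.
#' @return The p-distance in `[0, 1]`, or `NA`.
#' @export
pdistance <- function(aln, i, j) {
  aln <- as_alignment(aln)
  stopifnot(!identical(i, j))
  a <- strsplit(aln[[i]], "")[[1L]]
  b <- strsplit(aln[[j]], "")[[1L]]
  ok <- !(a %in% c("-", "X")) & !(b %in% c("-", "X"))
  if (!any(ok)) return(NA_real_)
  sum(a[ok] != b[ok]) / sum(ok)
}

#' Poisson correction of a p-distance
#'
#' `d = -ln(1 - p)`, the expected number of amino-acid substitutions per
#' site under a Poisson model.  Saturated inputs (`p >= 1`) give `NA` with
#' a warning.
#'
#' @param p Proportion(s) of differing sites in `[0, 1)`.
#' @return Distance(s) in substitutions per site.
#' @export
poisson_correct <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 | is.na(p)))
  sat <- !is.na(p) & p >= 1
  if (any(sat)) {
    warning("saturated p-distance(s) (p >= 1) set to NA")
    p[sat] <- NA_real_
  }
  -log(1 - p)
}

#' Pairwise distance matrix of an alignment
#'
#' @param aln An alignment (see [as_alignment()]).
#' @param model `"poisson"` (Poisson-corrected, default) or `"p"` (raw
#'   p-distance).
#' @return A symmetric matrix with zero diagonal; `NA` marks pairs with no
#'   comparable sites (or saturation under `"poisson"`).
#' @export
pdistance_matrix <- function(aln, model = c("poisson", "p")) {
  model <- match.arg(model)
  aln <- as_alignment(aln)
  m <- .aln_matrix(aln)
  n <- nrow(m)
  usable <- !(m == "-" | m == "X")
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- usable[i, ] & usable[j, ]
      p <- if (!any(ok)) NA_real_ else sum(m[i, ok] != m[j, ok]) / sum(ok)
      d[i, j] <- d[j, i] <- p
    }
  }
  if (model == "poisson") {
    diag(d) <- NA
    d[] <- suppressWarnings(poisson_correct(d))
    if (any(!is.na(d) & is.infinite(d))) d[is.infinite(d)] <- NA
    diag(d) <- 0
  }
  d
}

.fmt_len <- function(x) sprintf("%.15g", x)

#' Neighbor-joining tree from a distance matrix
#'
#' The Saitou-Nei algorithm: iteratively join the pair minimizing the
#' Q-criterion, compute branch lengths to the new node, reduce the matrix.
#' Negative branch lengths are by default clamped to zero with the deficit
#' transferred to the sister branch; set `clamp_negative = FALSE` for raw
#' values.
#'
#' @param d A symmetric distance matrix (or `dist`) over at least 3 taxa;
#'   `NA` entries are rejected.
#' @param clamp_negative Clamp negative branch lengths (default TRUE)?
#' @return An unrooted [ape] `phylo` tree with branch lengths.
#' @export
nj_tree <- function(d, clamp_negative = TRUE) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d), !is.null(rownames(d)))
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (any(is.na(d))) {
    stop("distance matrix has missing entries; trim the alignment so every ",
         "pair retains comparable sites")
  }
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  labs <- rownames(d)
  reps <- labs
  D <- unname(d)
  active <- seq_len(nrow(D))
  clamp2 <- function(li, lj) {
    if (!clamp_negative) return(c(li, lj))
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(0, li + lj); lj <- 0 }
    c(li, lj)
  }
  while (length(active) > 3L) {
    n <- length(active)
    Dm <- D[active, active]
    r <- rowSums(Dm)
    Q <- (n - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    k <- which(Q == min(Q), arr.ind = TRUE)
    k <- k[order(k[, 1L], k[, 2L]), , drop = FALSE][1L, ]
    i <- min(k)
    j <- max(k)
    ai <- active[i]
    aj <- active[j]
    li <- Dm[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- Dm[i, j] - li
    ll <- clamp2(li, lj)
    newd <- (D[ai, active] + D[aj, active] - Dm[i, j]) / 2
    u <- nrow(D) + 1L
    D <- rbind(cbind(D, 0), 0)
    D[u, active] <- newd
    D[active, u] <- newd
    D[u, u] <- 0
    reps[u] <- paste0("(", reps[ai], ":", .fmt_len(ll[1L]), ",",
                      reps[aj], ":", .fmt_len(ll[2L]), ")")
    active <- c(setdiff(active, c(ai, aj)), u)
  }
  idx <- active
  lens <- c((D[idx[1L], idx[2L]] + D[idx[1L], idx[3L]] - D[idx[2L], idx[3L]]) / 2,
            (D[idx[1L], idx[2L]] + D[idx[2L], idx[3L]] - D[idx[1L], idx[3L]]) / 2,
            (D[idx[1L], idx[3L]] + D[idx[2L], idx[3L]] - D[idx[1L], idx[2L]]) / 2)
  if (clamp_negative) {
    # transfer each deficit to the closest sister at the trifurcation
    for (i in 1:3) {
      if (lens[i] < 0) {
        others <- setdiff(1:3, i)
        sis <- others[which.min(D[idx[i], idx[others]])]
        lens[sis] <- lens[sis] + lens[i]
        lens[i] <- 0
      }
    }
    lens <- pmax(0, lens)
  }
  txt <- paste0("(", reps[idx[1L]], ":", .fmt_len(lens[1L]), ",",
                reps[idx[2L]], ":", .fmt_len(lens[2L]), ",",
                reps[idx[3L]], ":", .fmt_len(lens[3L]), ");")
  ape::read.tree(text = txt)
}

#' Neighbor-joining with bootstrap supports
#'
#' Each replicate resamples alignment columns with replacement and rebuilds
#' Poisson-corrected distances and the NJ tree.  Supports are the
#' percentage of replicates containing each bipartition of the full-data
#' tree (`type = "full"`, default, the tree that is reported) or of the
#' majority-rule consensus (`type = "consensus"`).  Replicates whose
#' resampled distances are undefined are redrawn (at most 10 times each).
#'
#' @param aln An alignment (see [as_alignment()]).
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed; identical seeds give identical
#'   supports.
#' @param type Report the full-data NJ tree or the majority-rule consensus.
#' @param clamp_negative Passed to [nj_tree()].
#' @return A `phylo` tree whose `node.label` holds supports in `[0, 100]`.
#' @export
bootstrap_consensus <- function(aln, replicates = 1000, seed = NULL,
                                type = c("full", "consensus"),
                                clamp_negative = TRUE) {
  type <- match.arg(type)
  aln <- as_alignment(aln)
  L <- nchar(aln[[1L]])
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
            add = TRUE)
    set.seed(seed)
  }
  m <- .aln_matrix(aln)
  full <- nj_tree(pdistance_matrix(aln), clamp_negative = clamp_negative)
  trees <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    for (try in 1:10) {
      cols <- sample.int(L, L, replace = TRUE)
      sub <- setNames(apply(m[, cols, drop = FALSE], 1L, paste,
                            collapse = ""), names(aln))
      dd <- pdistance_matrix(sub)
      if (!any(is.na(dd))) break
      .msg("bootstrap replicate ", r, " had undefined distances; redrawn")
      if (try == 10L) stop("bootstrap replicate kept producing undefined ",
                           "distances; trim the alignment")
    }
    trees[[r]] <- nj_tree(dd, clamp_negative = clamp_negative)
  }
  class(trees) <- "multiPhylo"
  ref <- if (type == "full") full else ape::consensus(trees, p = 0.5)
  counts <- ape::prop.clades(ref, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  ref$node.label <- as.character(round(100 * counts / replicates))
  ref
}

#' Majority consensus sequence of an alignment
#'
#' Per column the most frequent non-gap residue is emitted when its
#' frequency (relative to the number of rows) reaches
#' `majority_threshold`, else `x`; ties break alphabetically; columns that
#' are majority-gap are dropped.
#'
#' @param aln An alignment (see [as_alignment()]).
#' @param majority_threshold Minimum frequency (default 0.5).
#' @return The consensus as a character scalar.
#' @export
consensus_sequence <- function(aln, majority_threshold = 0.5) {
  aln <- as_alignment(aln)
  m <- .aln_matrix(aln)
  n <- nrow(m)
  keep <- colMeans(m == "-") <= 0.5
  out <- vapply(which(keep), function(j) {
    col <- m[, j]
    col <- col[!col %in% c("-", "X")]
    if (!length(col)) return("x")
    tab <- table(col)
    top <- sort(names(tab)[tab == max(tab)])[1L]
    if (max(tab) / n >= majority_threshold) top else "x"
  }, character(1L))
  paste(out, collapse = "")
}

#' Write a tree to newick
#'
#' Branch lengths are preserved; internal-node labels (bootstrap support
#' percentages) are written when present.
#'
#' @param tree An ape `phylo` tree with labeled leaves.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label)) ||
      anyNA(tree$tip.label)) {
    stop("tree has unlabeled leaves")
  }
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
  if (!is.null(tree$node.label)) {
    sup <- suppressWarnings(as.numeric(tree$node.label))
    bad <- !is.na(sup) & (sup < 0 | sup > 100)
    if (any(bad)) stop("support labels must lie in [0, 100]")
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Place query domains on a reference tree
#'
#' Builds an NJ tree over query and labeled reference domains from
#' normalized local-alignment score distances, then labels each query with
#' the majority subfamily of the smallest clade that joins it to at least
#' one reference.
#'
#' @param peptides Named character vector (or `AAStringSet`) of query
#'   domains.
#' @param references Named [Biostrings::AAStringSet]; names start with the
#'   subfamily label (see [assign_subfamily()]).
#' @param config A [scan_config()] (alignment parameters).
#' @return Named character vector: query name to clade label.
#' @export
placements_from_tree <- function(peptides, references,
                                 config = scan_config()) {
  if (is(peptides, "XStringSet")) {
    peptides <- setNames(as.character(peptides), names(peptides))
  }
  references <- .as_queries(references)
  stopifnot(length(peptides) >= 1L, !is.null(names(peptides)))
  mat <- .substitution_matrix(config)
  seqs <- c(peptides, setNames(as.character(references),
                               paste0("ref|", names(references))))
  n <- length(seqs)
  if (anyDuplicated(names(seqs))) stop("duplicate sequence names")
  self <- vapply(seqs, .self_score, numeric(1L), mat = mat)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    sc <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAStringSet(seqs[(i + 1L):n]),
      subject = seqs[[i]], type = "local", substitutionMatrix = mat,
      gapOpening = config$gap_opening, gapExtension = config$gap_extension,
      scoreOnly = TRUE)
    dv <- pmax(0, 1 - sc / pmin(self[i], self[(i + 1L):n]))
    d[i, (i + 1L):n] <- dv
    d[(i + 1L):n, i] <- dv
  }
  tree <- nj_tree(d)
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  tips_under <- function(node) {
    if (node <= ntip) return(node)
    unlist(lapply(kids[[as.character(node)]], tips_under))
  }
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  is_ref <- startsWith(tree$tip.label, "ref|")
  out <- vapply(names(peptides), function(q) {
    node <- which(tree$tip.label == q)
    repeat {
      node <- parent[node]
      if (node == 0L) return(NA_character_)
      tips <- tips_under(node)
      refs <- tips[is_ref[tips]]
      if (length(refs)) {
        labs <- .ref_label(sub("^ref\\|", "", tree$tip.label[refs]))
        tab <- sort(table(labs), decreasing = TRUE)
        return(names(tab)[1L])
      }
    }
  }, character(1L))
  out
}
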