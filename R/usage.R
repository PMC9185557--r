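#' V/J gene-segment usage profile
#'
#' Relative frequencies of the V or J gene segments flanking the CDR3
#' sequences of a sample. Ambiguous and unknown gene assignments are
#' excluded and the remaining mass renormalised. Template weighting
#' (default) weights each clonotype by its template count, i.e. usage as
#' a fraction of sequenced mass; clonotype weighting counts each unique
#' clonotype once.
#'
#' @param rep a `tcr_repertoire` (productive records are used).
#' @param segment_class `"V"` or `"J"`.
#' @param weighting `"template"` (default) or `"clonotype"`.
#' @return object of class `usage_profile`: list with `sample_id`,
#'   `segment_class`, `weighting` and `frequencies` (named numeric
#'   vector summing to 1).
#' @export
usage_profile <- function(rep, segment_class = c("V", "J"),
                          weighting = c("template", "clonotype")) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  segment_class <- match.arg(segment_class)
  weighting <- match.arg(weighting)
  rec <- rep$records[rep$records$productive, ]
  gene <- if (segment_class == "V") rec$v_gene else rec$j_gene
  keep <- !gene %in% GENE_SENTINELS
  if (!any(keep)) {
    stop("all ", segment_class, " gene calls are ambiguous/unknown",
         call. = FALSE)
  }
  w <- if (weighting == "template") rec$templates[keep] else rep(1, sum(keep))
  agg <- tapply(w, gene[keep], sum)
  freqs <- as.numeric(agg) / sum(agg)
  structure(
    list(sample_id = rep$sample_id,
         segment_class = segment_class,
         weighting = weighting,
         frequencies = stats::setNames(freqs, names(agg))),
    class = "usage_profile"
  )
}

#' @export
print.usage_profile <- function(x, ...) {
  cat(sprintf("<usage_profile> sample %s, %s genes (%s-weighted)\n",
              x$sample_id, x$segment_class, x$weighting))
  print(round(sort(x$frequencies, decreasing = TRUE), 4))
  invisible(x)
}

#' CDR3 length-by-gene spectratype matrix
#'
#' Joint template-frequency matrix of CDR3 amino-acid length (rows)
#' against gene segment (columns) — the tabular form of a CDR3
#' spectratyping plot. Ambiguous/unknown gene calls are excluded and the
#' matrix renormalised so that the grand total is 1. Row sums give the
#' CDR3 length distribution; column sums reproduce the template-weighted
#' usage profile.
#'
#' @inheritParams usage_profile
#' @return numeric matrix; `rownames` are lengths, `colnames` gene
#'   labels.
#' @export
spectratype <- function(rep, segment_class = c("V", "J")) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  segment_class <- match.arg(segment_class)
  rec <- rep$records[rep$records$productive, ]
  gene <- if (segment_class == "V") rec$v_gene else rec$j_gene
  keep <- !gene %in% GENE_SENTINELS
  if (!any(keep)) {
    stop("all ", segment_class, " gene calls are ambiguous/unknown",
         call. = FALSE)
  }
  len <- nchar(rec$cdr3_aa[keep])
  tab <- tapply(rec$templates[keep], list(len, gene[keep]), sum,
                default = 0)
  tab / sum(tab)
}

#' Jensen-Shannon divergence between two usage profiles
#'
#' \eqn{JSD(P,Q) = \frac12 KL(P\|M) + \frac12 KL(Q\|M)} with
#' \eqn{M = (P+Q)/2}, computed in base 2 so the value is bounded in
#' [0, 1] (0 for identical profiles, 1 for disjoint supports). The union
#' of supports is taken, absent genes contributing frequency 0, with the
#' convention \eqn{0 \log 0 = 0}.
#'
#' @param p,q `usage_profile` objects of the same segment class, or
#'   plain named frequency vectors.
#' @return divergence in [0, 1].
#' @export
js_divergence <- function(p, q) {
  fp <- if (inherits(p, "usage_profile")) p$frequencies else p
  fq <- if (inherits(q, "usage_profile")) q$frequencies else q
  if (inherits(p, "usage_profile") && inherits(q, "usage_profile") &&
      p$segment_class != q$segment_class) {
    stop("profiles are for different segment classes", call. = FALSE)
  }
  support <- union(names(fp), names(fq))
  a <- stats::setNames(rep(0, length(support)), support)
  b <- a
  a[names(fp)] <- fp
  b[names(fq)] <- fq
  m <- (a + b) / 2
  kl <- function(x, y) {
    nz <- x > 0
    sum(x[nz] * log2(x[nz] / y[nz]))
  }
  0.5 * kl(a, m) + 0.5 * kl(b, m)
}

#' Pairwise Jensen-Shannon divergence matrix
#'
#' @param profiles list of `usage_profile` objects of one segment class.
#' @return symmetric numeric matrix with sample ids as dimnames.
#' @export
jsd_matrix <- function(profiles) {
  n <- length(profiles)
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- js_divergence(profiles[[i]], profiles[[j]])
    }
  }
  m
}

#' Unsupervised clustering of gene-usage profiles
#'
#' Builds the pairwise Jensen-Shannon divergence matrix, embeds the
#' samples in 2-D by classical metric scaling of the square-root
#' divergence (the square root of JSD is a true metric, which classical
#' scaling assumes), and clusters: hierarchical uses average linkage on
#' the metric distances; k-means runs on the 2-D embedding with 10
#' restarts under a fixed seed; density mode returns the connected
#' components of the graph joining samples with JSD at or below `eps`
#' (singleton components are reported as cluster 0 when
#' `min_members > 1`).
#'
#' @param profiles list of at least 3 `usage_profile` objects.
#' @param method `"hierarchical"`, `"kmeans"` or `"density"`.
#' @param k number of clusters (hierarchical, kmeans); must not exceed
#'   the number of profiles.
#' @param eps JSD neighbourhood radius (density mode; required, no
#'   default is claimed).
#' @param min_members minimum component size reported as a cluster in
#'   density mode (default 2).
#' @param seed RNG seed for k-means restarts.
#' @return list with `assignment` (named integer vector), `embedding`
#'   (n x 2 matrix), `jsd` (divergence matrix), `method`.
#' @export
usage_cluster <- function(profiles, method = c("hierarchical", "kmeans", "density"),
                          k = 2, eps = NULL, min_members = 2, seed = 1) {
  method <- match.arg(method)
  n <- length(profiles)
  if (n < 3) stop("need at least 3 profiles", call. = FALSE)
  jsd <- jsd_matrix(profiles)
  d <- stats::as.dist(sqrt(jsd))
  emb <- if (all(jsd == 0)) {
    matrix(0, n, 2, dimnames = list(rownames(jsd), NULL))
  } else {
    e <- stats::cmdscale(d, k = 2)
    if (ncol(e) < 2) e <- cbind(e, 0)
    e
  }
  assignment <- switch(method,
    hierarchical = {
      if (k > n) stop("k exceeds the number of profiles", call. = FALSE)
      stats::cutree(stats::hclust(d, method = "average"), k = k)
    },
    kmeans = {
      if (k > n) stop("k exceeds the number of profiles", call. = FALSE)
      set.seed(seed)
      km <- stats::kmeans(emb, centers = k, nstart = 10)
      stats::setNames(km$cluster, rownames(jsd))
    },
    density = {
      if (is.null(eps)) stop("density mode requires eps", call. = FALSE)
      comp <- connected_components(jsd <= eps)
      sizes <- table(comp)
      comp[sizes[as.character(comp)] < min_members] <- 0L
      stats::setNames(relabel_clusters(comp), rownames(jsd))
    }
  )
  list(assignment = assignment, embedding = emb, jsd = jsd, method = method)
}

# connected components of a logical adjacency matrix (union-find)
connected_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n)) {
    for (j in which(adj[i, ])) {
      if (j > i) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# renumber clusters 1..K keeping 0 (noise) as is
relabel_clusters <- function(x) {
  pos <- x > 0
  x[pos] <- match(x[pos], unique(x[pos]))
  x
}
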