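#' Levenshtein distance between CDR3 amino-acid sequences
#'
#' Standard unit-cost edit distance (substitutions, insertions,
#' deletions), vectorised over pairs.
#'
#' @param a,b character vectors of non-empty amino-acid sequences
#'   (recycled to a common length).
#' @return integer vector of distances.
#' @export
levenshtein <- function(a, b) {
  if (any(is.na(a)) || any(is.na(b)) || any(a == "") || any(b == "")) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  out <- integer(n)
  for (i in seq_len(n)) out[i] <- utils::adist(a[i], b[i])
  out
}

# pairwise distance matrix between two sequence sets, with a length
# prefilter: pairs whose lengths differ by more than max_dist cannot be
# within max_dist, so only compatible length buckets are computed.
bounded_distance_pairs <- function(qs, ts, max_dist) {
  ql <- nchar(qs); tl <- nchar(ts)
  res_q <- integer(0); res_t <- integer(0); res_d <- integer(0)
  for (L in unique(ql)) {
    qi <- which(ql == L)
    ti <- which(abs(tl - L) <= max_dist)
    if (length(ti) == 0) next
    d <- utils::adist(qs[qi], ts[ti])
    hit <- which(d <= max_dist, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      res_q <- c(res_q, qi[hit[, 1]])
      res_t <- c(res_t, ti[hit[, 2]])
      res_d <- c(res_d, d[hit])
    }
  }
  list(query = res_q, target = res_t, distance = res_d)
}

#' Cluster CDR3 sequences across samples by bounded edit distance
#'
#' Builds the graph joining CDR3 amino-acid sequences whose Levenshtein
#' distance is at most `max_dist` (optionally restricted to pairs with
#' the same V gene) and returns its connected components as clusters.
#' This exact formulation reproduces, for small edit bounds, the
#' cluster structure that accelerated CDR3-clustering tools approximate;
#' a length-bucketing prefilter (sequences whose lengths differ by more
#' than `max_dist` cannot be neighbours) keeps it fast at desk scale.
#' Components spanning at least two patients are flagged as shared.
#'
#' @param samples list of `tcr_repertoire` objects, or a data frame with
#'   columns `cdr3_aa`, `v_gene`, `patient_id`.
#' @param max_dist maximum Levenshtein distance for an edge
#'   (non-negative; default 1).
#' @param same_vgene additionally require identical V genes on an edge
#'   (default FALSE: reported cross-patient clusters are sequence-level).
#' @return tibble with one row per cluster: `cluster_id`, `members`
#'   (list of sequences), `patients` (list), `n_members`, `n_patients`,
#'   `representative` (lexicographically smallest member), `max_dist`
#'   (maximum pairwise member distance) and `shared`.
#' @export
cluster_cdr3 <- function(samples, max_dist = 1, same_vgene = FALSE) {
  stopifnot(max_dist >= 0)
  tab <- if (is.data.frame(samples)) {
    tibble::as_tibble(samples)
  } else {
    dplyr::bind_rows(lapply(samples, function(r) {
      rec <- r$records[r$records$productive, ]
      tibble::tibble(cdr3_aa = rec$cdr3_aa, v_gene = rec$v_gene,
                     patient_id = r$patient_id)
    }))
  }
  tab <- dplyr::distinct(tab, .data$cdr3_aa, .data$v_gene, .data$patient_id)
  units <- if (same_vgene) {
    dplyr::distinct(tab, .data$cdr3_aa, .data$v_gene)
  } else {
    dplyr::distinct(tab, .data$cdr3_aa) |> dplyr::mutate(v_gene = NA_character_)
  }
  n <- nrow(units)
  pairs <- bounded_distance_pairs(units$cdr3_aa, units$cdr3_aa, max_dist)
  keep <- pairs$query < pairs$target
  if (same_vgene) {
    keep <- keep & units$v_gene[pairs$query] == units$v_gene[pairs$target]
  }
  adj_i <- pairs$query[keep]
  adj_j <- pairs$target[keep]
  comp <- components_from_edges(n, adj_i, adj_j)
  units$component <- comp
  membership <- if (same_vgene) {
    dplyr::left_join(tab, units, by = c("cdr3_aa", "v_gene"))
  } else {
    dplyr::left_join(tab, units[c("cdr3_aa", "component")], by = "cdr3_aa")
  }
  out <- membership |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(
      members = list(sort(unique(.data$cdr3_aa))),
      patients = list(sort(unique(.data$patient_id))),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_members = lengths(.data$members),
      n_patients = lengths(.data$patients),
      representative = vapply(.data$members, `[`, character(1), 1),
      shared = .data$n_patients >= 2
    )
  out$max_dist <- vapply(out$members, function(m) {
    if (length(m) < 2) return(0L)
    as.integer(max(utils::adist(m)))
  }, integer(1))
  out |>
    dplyr::arrange(dplyr::desc(.data$n_members), .data$representative) |>
    dplyr::mutate(cluster_id = dplyr::row_number()) |>
    dplyr::select("cluster_id", "representative", "members", "patients",
                  "n_members", "n_patients", "max_dist", "shared")
}

# union-find over an edge list
components_from_edges <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_along(from)) {
    ri <- find(from[e]); rj <- find(to[e])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Build a composite CDR3 reference library
#'
#' Pools per-sample CDR3 clone tables (e.g. clones extracted from tumour
#' RNA-seq of an external cohort) into one reference library, excluding
#' samples with `min_clones` or fewer detectable clones, and builds a
#' deduplicated sequence index retaining per-sequence source sample
#' lists.
#'
#' @param clone_tables named list of data frames, each with a `cdr3_aa`
#'   column (a `count` column is carried through when present); names
#'   are sample ids.
#' @param min_clones samples must have strictly more than this many
#'   clones to be retained (default 3).
#' @return object of class `composite_library`: list with `entries`
#'   (tibble of cdr3_aa, source, count), `unique_index` (tibble of
#'   cdr3_aa with list-column `sources`), `n_samples_retained`.
#' @export
build_composite_library <- function(clone_tables, min_clones = 3) {
  if (is.null(names(clone_tables)) || any(names(clone_tables) == "")) {
    names(clone_tables) <- paste0("sample", seq_along(clone_tables))
  }
  keep <- vapply(clone_tables, function(t) nrow(t) > min_clones, logical(1))
  if (!any(keep)) {
    stop("no samples exceed the minimum clone count of ", min_clones,
         call. = FALSE)
  }
  entries <- dplyr::bind_rows(lapply(names(clone_tables)[keep], function(id) {
    t <- clone_tables[[id]]
    tibble::tibble(
      cdr3_aa = toupper(as.character(t$cdr3_aa)),
      source = id,
      count = if ("count" %in% names(t)) as.numeric(t$count) else 1
    )
  }))
  unique_index <- entries |>
    dplyr::group_by(.data$cdr3_aa) |>
    dplyr::summarise(sources = list(sort(unique(.data$source))),
                     total_count = sum(.data$count), .groups = "drop")
  structure(
    list(entries = entries, unique_index = unique_index,
         n_samples_retained = sum(keep)),
    class = "composite_library"
  )
}

#' @export
print.composite_library <- function(x, ...) {
  cat(sprintf(
    "<composite_library> %d clones (%d unique) pooled from %d samples\n",
    nrow(x$entries), nrow(x$unique_index), x$n_samples_retained))
  invisible(x)
}

#' Query a composite library by bounded edit distance
#'
#' Returns every library sequence within `max_dist` Levenshtein
#' distance of each query, with its source samples — the mechanics of
#' matching repertoire clonotypes against an external reference library
#' of CDR3 sequences.
#'
#' @param queries character vector of CDR3 amino-acid sequences.
#' @param lib a `composite_library`.
#' @param max_dist maximum Levenshtein distance (default 1).
#' @return tibble with `query`, `match`, `distance`, `sources`
#'   (list-column); zero rows when nothing matches.
#' @export
query_library <- function(queries, lib, max_dist = 1) {
  stopifnot(inherits(lib, "composite_library"), max_dist >= 0)
  queries <- toupper(queries)
  idx <- lib$unique_index
  pairs <- bounded_distance_pairs(queries, idx$cdr3_aa, max_dist)
  tibble::tibble(
    query = queries[pairs$query],
    match = idx$cdr3_aa[pairs$target],
    distance = as.integer(pairs$distance),
    sources = idx$sources[pairs$target]
  ) |>
    dplyr::arrange(.data$query, .data$distance, .data$match)
}

#' Position-frequency matrix of equal-length CDR3 sequences
#'
#' Counts amino-acid occurrences per position across a set of
#' equal-length sequences and normalises each position to 1 — the matrix
#' behind a sequence logo plot. Mixed lengths raise an error directing
#' the caller to group by length, unless a `pad` character is given, in
#' which case shorter sequences are right-padded and the pad character
#' is counted as its own row.
#'
#' @param sequences character vector of CDR3 amino-acid sequences.
#' @param pad optional single padding character (e.g. `"-"`).
#' @return numeric matrix, rows = residues (20 amino acids, plus the pad
#'   character if used), columns = positions; every column sums to 1.
#' @export
motif_matrix <- function(sequences, pad = NULL) {
  if (length(sequences) == 0) stop("no sequences", call. = FALSE)
  lens <- nchar(sequences)
  if (length(unique(lens)) > 1) {
    if (is.null(pad)) {
      stop("sequences have mixed lengths; group them by length or supply pad",
           call. = FALSE)
    }
    stopifnot(nchar(pad) == 1)
    width <- max(lens)
    sequences <- vapply(sequences, function(s) {
      paste0(s, strrep(pad, width - nchar(s)))
    }, character(1))
  }
  width <- nchar(sequences[1])
  alphabet <- c(AA_ALPHABET, if (!is.null(pad)) pad)
  chars <- matrix(unlist(strsplit(sequences, "")), ncol = width, byrow = TRUE)
  m <- vapply(seq_len(width), function(j) {
    tab <- table(factor(chars[, j], levels = alphabet))
    as.numeric(tab) / length(sequences)
  }, numeric(length(alphabet)))
  rownames(m) <- alphabet
  colnames(m) <- seq_len(width)
  m
}
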