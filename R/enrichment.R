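#' Read a GMT gene-set collection
#'
#' GMT format: one set per line, tab-separated — set name, description, then
#' member gene ids. Duplicate members within a set are deduplicated; duplicate
#' set names are an error.
#'
#' @param path path to a `.gmt` file.
#' @return named list of character vectors (the sets), with attribute
#'   `source` = the file path.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("malformed GMT line ", i, ": expected name, description, members")
    nm <- parts[1]
    if (nm %in% names(sets)) stop("duplicated set name: ", nm)
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) stop("malformed GMT line ", i, ": empty set")
    sets[[nm]] <- members
  }
  attr(sets, "source") <- path
  sets
}

#' Over-representation analysis
#'
#' One-sided Fisher's exact (hypergeometric upper-tail) test of a query gene
#' list against each set in a collection. Sets are first intersected with the
#' universe; sets smaller than `min_size` within the universe are excluded.
#' P-values are Benjamini-Hochberg adjusted across the tested sets and sets
#' with adjusted p below `alpha` are flagged.
#'
#' @param query character vector of genes of interest; must be a subset of
#'   `universe`.
#' @param universe character vector of all eligible genes (e.g. every gene
#'   surviving the integration filters).
#' @param sets named list of gene sets (see [read_gmt()]).
#' @param min_size minimum set size within the universe (default 10).
#' @param alpha adjusted-p significance cutoff (default 0.1).
#' @return data.frame with one row per tested set: `set`, `k` (overlap),
#'   `K` (set size in universe), `n` (query size), `N` (universe size),
#'   `pval`, `qval`, `significant`, `members` (overlap ids, comma-joined).
#' @export
ora <- function(query, universe, sets, min_size = 10, alpha = 0.1) {
  query <- unique(query)
  universe <- unique(universe)
  bad <- setdiff(query, universe)
  if (length(bad) > 0)
    stop("query gene(s) not in universe: ", paste(bad, collapse = ", "))
  n <- length(query)
  N <- length(universe)
  in_univ <- lapply(sets, intersect, universe)
  keep <- vapply(in_univ, length, 0L) >= min_size
  in_univ <- in_univ[keep]
  if (length(in_univ) == 0)
    return(data.frame(set = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), pval = numeric(),
                      qval = numeric(), significant = logical(),
                      members = character(), stringsAsFactors = FALSE))
  rows <- lapply(names(in_univ), function(nm) {
    s <- in_univ[[nm]]
    hit <- intersect(query, s)
    k <- length(hit)
    K <- length(s)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, pval = p,
               qval = NA_real_, significant = NA,
               members = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$qval <- bh_adjust(out$pval)
  out$significant <- out$qval < alpha
  out <- out[order(out$pval, out$set), ]
  rownames(out) <- NULL
  out
}
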