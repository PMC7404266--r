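#' Read gene sets from GMT
#'
#' Each GMT line is `name<TAB>description<TAB>member1<TAB>member2...`.
#' Members are deduplicated within a set. An empty file yields an empty
#' collection; a line with fewer than three fields is a parse error.
#'
#' @param path Path to a GMT file, or a character vector of lines.
#' @return A list of class `GeneSetCollection` with elements `sets` (named
#'   list of character vectors) and `descriptions` (named character vector).
#' @export
readGmt <- function(path) {
  if (length(path) == 1L && !grepl("\n", path) && file.exists(path)) {
    lines <- readLines(path)
  } else {
    lines <- unlist(strsplit(as.character(path), "\n", fixed = TRUE))
  }
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields")
    sets[[f[1L]]] <- unique(f[-(1:2)])
    desc[f[1L]] <- f[2L]
  }
  structure(list(sets = sets, descriptions = desc), class = "GeneSetCollection")
}

#' Hypergeometric over-representation test
#'
#' For each gene set, tests whether the query list overlaps the set more than
#' expected by chance under sampling without replacement from the background
#' universe: with `N = |background|`, `K = |set` \eqn{\cap} `background|`,
#' `n = |query|` and overlap `k`, the one-sided upper-tail p-value is
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`. P-values are adjusted
#' across sets by Benjamini-Hochberg and results are sorted by p.
#'
#' @param query Character vector of query gene ids (must lie within
#'   `background`).
#' @param collection A `GeneSetCollection` from [readGmt()], or a named list
#'   of character vectors.
#' @param background Character vector: the gene universe.
#' @return `data.frame`: set, overlap, set_size (members in background), p,
#'   p_adj, sorted by p.
#' @examples
#' bg <- paste0("g", 1:10)
#' gs <- list(A = paste0("g", 1:5))
#' overrepresentationTest(paste0("g", 1:5), gs, bg)  # p = 1/choose(10,5)
#' @export
overrepresentationTest <- function(query, collection, background) {
  sets <- if (inherits(collection, "GeneSetCollection")) collection$sets else collection
  stopifnot(is.list(sets), length(names(sets)) == length(sets))
  query <- unique(query)
  background <- unique(background)
  off <- setdiff(query, background)
  if (length(off))
    stop("query gene(s) outside the background universe: ",
         paste(off, collapse = ", "))
  N <- length(background); n <- length(query)
  res <- lapply(names(sets), function(nm) {
    K <- length(intersect(sets[[nm]], background))
    k <- length(intersect(query, sets[[nm]]))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    return(data.frame(set = character(), overlap = integer(),
                      set_size = integer(), p = numeric(), p_adj = numeric()))
  }
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
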