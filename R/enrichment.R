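#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance that a random draw
#' of n genes from a universe of N containing K category members captures at
#' least k of them. This is the over-representation p-value used for
#' gene-set enrichment.
#'
#' @param k Observed category members in the test set, 0 <= k <= K.
#' @param K Category size in the universe.
#' @param n Test-set size.
#' @param N Universe size.
#' @return Upper-tail probability; exactly 1 when k = 0.
#' @examples
#' hypergeom_tail(3, 3, 24, 123)  # 0.0067, prints as 0.007 at 1 s.f.
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (k < 0 || K < 0 || n < 0 || N < 0) stop("all arguments must be non-negative")
  if (k > K) stop("k cannot exceed K")
  if (K > N) stop("K cannot exceed N")
  if (n > N) stop("n cannot exceed N")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Build an annotation database
#'
#' @param categories Named list of character vectors (category id ->
#'   member genes), or a data frame from [read_gmt()].
#' @param universe Character vector of all annotated genes; defaults to the
#'   union of the category members.
#' @param names Optional named character vector of human-readable category
#'   names; GMT description fields when read from file.
#' @param namespaces Optional named character vector of category namespaces
#'   (e.g. GO-BP, MIPS).
#' @return Object of class `annotation_db`.
#' @export
annotation_db <- function(categories, universe = NULL, names = NULL,
                          namespaces = NULL) {
  stopifnot(is.list(categories), length(categories) >= 1L,
            !is.null(base::names(categories)))
  categories <- lapply(categories, unique)
  if (any(lengths(categories) < 1L)) stop("categories must have at least one member")
  if (is.null(universe)) universe <- unique(unlist(categories))
  out <- setdiff(unique(unlist(categories)), universe)
  if (length(out)) stop("category members outside the universe: ",
                        paste(utils::head(out, 5), collapse = ", "))
  structure(list(categories = categories, universe = unique(universe),
                 names = names, namespaces = namespaces),
            class = "annotation_db")
}

#' Read a GMT gene-set file
#'
#' One category per line: `category_id<TAB>name<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to the GMT file.
#' @param universe Optional universe passed through to [annotation_db()].
#' @return An [annotation_db()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) stop("GMT line(s) with fewer than 3 fields: line ",
                          paste(short, collapse = ", "))
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicated category ids in GMT: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  nms <- stats::setNames(vapply(fields, `[[`, "", 2L), ids)
  cats <- stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])), ids)
  annotation_db(cats, universe = universe, names = nms)
}

#' Write an annotation database to GMT
#'
#' @param db An [annotation_db()].
#' @param path Output path.
#' @export
write_gmt <- function(db, path) {
  ids <- names(db$categories)
  nms <- if (is.null(db$names)) ids else unname(db$names[ids])
  lines <- vapply(seq_along(ids), function(i) {
    paste(c(ids[i], nms[i], db$categories[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' Tests each annotation category for over-representation in a gene set,
#' either against the full annotation universe or against a user-defined
#' reference set (e.g. a screened library as its own background). Test-set
#' genes absent from the reference are dropped with a message. For each
#' category intersecting the reference, the p-value is the upper
#' hypergeometric tail with N = |reference|, n = |test in reference|,
#' K = |category in reference|, k = |category in test|.
#'
#' @param test_set Character vector of genes of interest.
#' @param db An [annotation_db()].
#' @param reference `"universe"` (default) or a character vector defining a
#'   custom reference set (itself intersected with the universe).
#' @param threshold Report categories with p <= threshold; default 0.01. Use
#'   `threshold = 1` to keep everything.
#' @return Data frame with `category`, `name`, `p`, `p_adj`
#'   (Benjamini-Hochberg, reported but not used for filtering), `k`, `K`,
#'   `n`, `N`, `genes` (comma-separated observed members), sorted by p.
#' @export
enrich <- function(test_set, db, reference = "universe", threshold = 0.01) {
  stopifnot(inherits(db, "annotation_db"))
  test_set <- unique(test_set)
  if (identical(reference, "universe")) {
    ref <- db$universe
  } else {
    ref <- intersect(unique(reference), db$universe)
  }
  dropped <- setdiff(test_set, ref)
  if (length(dropped)) {
    message(length(dropped), " test-set gene(s) absent from the reference were dropped")
  }
  ts <- intersect(test_set, ref)
  if (length(ts) == 0L) {
    warning("empty test set after restriction to the reference")
    return(data.frame(category = character(), name = character(), p = numeric(),
                      p_adj = numeric(), k = integer(), K = integer(),
                      n = integer(), N = integer(), genes = character(),
                      stringsAsFactors = FALSE))
  }
  N <- length(ref)
  n <- length(ts)
  rows <- lapply(names(db$categories), function(id) {
    Kset <- intersect(db$categories[[id]], ref)
    if (length(Kset) == 0L) return(NULL)
    obs <- intersect(Kset, ts)
    data.frame(category = id,
               name = if (is.null(db$names)) id else unname(db$names[id]),
               p = hypergeom_tail(length(obs), length(Kset), n, N),
               k = length(obs), K = length(Kset), n = n, N = N,
               genes = paste(sort(obs), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res <- res[res$p <= threshold, , drop = FALSE]
  res <- res[order(res$p, res$category), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("category", "name", "p", "p_adj", "k", "K", "n", "N", "genes")]
}

#' Format a p-value the way screening reports print it
#'
#' One significant figure below 0.01, otherwise four significant figures.
#'
#' @param p Numeric p-values.
#' @return Character vector.
#' @export
display_p <- function(p) {
  ifelse(p < 0.01, formatC(signif(p, 1), format = "g"),
         formatC(signif(p, 4), format = "g"))
}
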