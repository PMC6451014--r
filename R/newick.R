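#' Read a Newick tree
#'
#' Thin, validating wrapper around \code{ape::read.tree}. The input may be
#' a file path or a Newick string. Numeric internal-node labels in
#' \eqn{[0,1]} or \eqn{[0,100]} are interpreted as branch supports and
#' returned via [tree_supports()]; other labels are kept as plain strings.
#' Duplicate leaf labels, unbalanced parentheses and negative branch
#' lengths are errors, never repaired.
#'
#' @param x file path or Newick string.
#' @return an \code{ape} `phylo` object.
#' @export
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  txt <- if (!grepl("(", x, fixed = TRUE) && file.exists(x))
    paste(readLines(x), collapse = "") else x
  no <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  nc <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (no != nc)
    ps_stop("unbalanced parentheses in Newick input (", no, " '(' vs ",
            nc, " ')')")
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(text = txt)),
    error = function(e) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    ps_stop("failed to parse Newick input")
  if (anyDuplicated(tree$tip.label))
    ps_stop("duplicate leaf labels: ",
            paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                  collapse = ", "))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    ps_stop("negative branch length on input")
  tree
}

#' Branch supports carried on a tree
#'
#' @param tree a `phylo` object whose internal-node labels may be numeric
#'   supports (posterior probabilities in \eqn{[0,1]} or bootstrap
#'   percentages in \eqn{[0,100]}).
#' @return numeric vector of supports (NA where absent), or `NULL` when the
#'   labels are not interpretable as supports.
#' @export
tree_supports <- function(tree) {
  lab <- tree$node.label
  if (is.null(lab)) return(NULL)
  num <- suppressWarnings(as.numeric(lab))
  ok <- !is.na(num) | !nzchar(lab)
  if (!all(ok)) return(NULL)                     # genuine string labels
  if (all(is.na(num))) return(NULL)
  rng <- range(num, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 100) return(NULL)
  num
}

#' Write a tree as Newick
#'
#' @param tree a `phylo` object.
#' @param path optional output file; when `NULL` the Newick string is
#'   returned.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  s <- ape::write.tree(tree, digits = 12)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(path)
}

#' Read a taxon-to-group annotation table
#'
#' Two or three tab-separated columns: taxon, group, optional display
#' color. Used to color and to quantify lineage classes (for example
#' monofunctional versus bifunctional enzymes, or slow versus fast
#' evolving clades).
#'
#' @param path TSV file (a header line `taxon<TAB>group` is optional).
#' @return data.frame with columns `taxon`, `group` and optionally `color`.
#' @export
read_group_annotation <- function(path) {
  if (!file.exists(path)) ps_stop("no such file: ", path)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (tolower(df[1, 1]) == "taxon") df <- df[-1, , drop = FALSE]
  if (ncol(df) < 2) ps_stop("annotation needs taxon and group columns")
  names(df)[1:2] <- c("taxon", "group")
  if (ncol(df) >= 3) names(df)[3] <- "color"
  group_annotation(df)
}

#' Validate a taxon-to-group annotation
#'
#' @param df data.frame with columns `taxon`, `group`, optional `color`.
#' @return the validated data.frame (class `group_annotation`).
#' @export
group_annotation <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(c("taxon", "group") %in% names(df)))
    ps_stop("annotation needs 'taxon' and 'group' columns")
  df$taxon <- as.character(df$taxon)
  df$group <- as.character(df$group)
  if (anyDuplicated(df$taxon))
    ps_stop("duplicate annotated taxa: ",
            paste(unique(df$taxon[duplicated(df$taxon)]), collapse = ", "))
  if (any(!nzchar(df$group))) ps_stop("empty group label")
  rownames(df) <- NULL
  class(df) <- c("group_annotation", "data.frame")
  df
}
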