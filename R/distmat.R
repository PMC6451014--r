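#' Construct an evolutionary distance matrix
#'
#' The symmetric matrix of original-space distances between taxa, in
#' expected substitutions per site. This is the object the Sammon mapping
#' embeds and neighbor-joining resolves into a tree. Pairs whose distance
#' was capped at the saturation bound are carried along as flags so that
#' downstream scenes can mark them.
#'
#' @param d square numeric matrix (or `dist`) of pairwise distances.
#' @param labels taxon identifiers; defaults to `rownames(d)`.
#' @param saturated two-column character matrix/data.frame of label pairs
#'   whose distance was capped, or `NULL`.
#' @param tol asymmetry tolerated (and averaged away) before erroring.
#' @return an object of class `evodist` with elements `labels`, `d`
#'   (dimnamed matrix) and `saturated`.
#' @export
evodist <- function(d, labels = NULL, saturated = NULL, tol = 1e-6) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) ps_stop("distance matrix is not square")
  labels <- labels %||% rownames(d) %||% paste0("t", seq_len(nrow(d)))
  labels <- as.character(labels)
  if (length(labels) != nrow(d))
    ps_stop("matrix order ", nrow(d), " does not match ", length(labels),
            " labels")
  if (anyDuplicated(labels))
    ps_stop("duplicate labels: ",
            paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (any(!is.finite(d))) ps_stop("non-finite distance entries")
  if (any(d < 0)) {
    bad <- which(d < 0, arr.ind = TRUE)[1, ]
    ps_stop("negative distance (", d[bad[1], bad[2]], ") between '",
            labels[bad[1]], "' and '", labels[bad[2]], "'")
  }
  asym <- max(abs(d - t(d)))
  if (asym > tol)
    ps_stop("matrix asymmetric beyond tolerance (max |d_ij - d_ji| = ",
            format(asym), ")")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(labels, labels)
  if (!is.null(saturated)) {
    saturated <- as.matrix(saturated)
    if (ncol(saturated) != 2) ps_stop("saturated must have two columns")
    unknown <- setdiff(c(saturated), labels)
    if (length(unknown))
      ps_stop("saturated pair references unknown taxa: ",
              paste(unknown, collapse = ", "))
  }
  structure(list(labels = labels, d = d, saturated = saturated),
            class = "evodist")
}

#' @export
as.matrix.evodist <- function(x, ...) x$d

#' @export
as.dist.evodist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$d, diag = diag, upper = upper)
}

#' @export
print.evodist <- function(x, ...) {
  n <- length(x$labels)
  cat("evodist:", n, "taxa,", n * (n - 1) / 2, "pairs")
  if (!is.null(x$saturated) && nrow(x$saturated))
    cat(",", nrow(x$saturated), "saturated pair(s)")
  cat("\n")
  print(round(x$d[seq_len(min(n, 6)), seq_len(min(n, 6))], 4))
  if (n > 6) cat("...\n")
  invisible(x)
}

.phylip_names <- function(labels) {
  nm <- substr(labels, 1, 10)
  if (anyDuplicated(nm))
    ps_stop("taxon names collide after truncation to 10 characters: ",
            paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sprintf("%-10s", nm)
}

#' Write a distance matrix
#'
#' The `phylip_square` dialect reproduces the classic protdist output
#' layout (taxon count on the first line, 10-character name field,
#' 6-decimal fixed point distances) so files drop into any tool that
#' consumes protdist matrices. Truncation collisions are a hard error.
#'
#' @param dm an [evodist()].
#' @param path output file.
#' @param dialect `"phylip_square"` or `"tsv"`.
#' @export
write_distance_matrix <- function(dm, path,
                                  dialect = c("phylip_square", "tsv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(dm, "evodist"))
  if (dialect == "phylip_square") {
    nm <- .phylip_names(dm$labels)
    rows <- vapply(seq_along(dm$labels), function(i)
      paste0(nm[i], " ", paste(sprintf("%.6f", dm$d[i, ]), collapse = " ")),
      character(1))
    writeLines(c(format(length(dm$labels)), rows), path)
  } else {
    lines <- c(paste(c("taxon", dm$labels), collapse = "\t"),
               vapply(seq_along(dm$labels), function(i)
                 paste(c(dm$labels[i], sprintf("%.6f", dm$d[i, ])),
                       collapse = "\t"), character(1)))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a distance matrix
#'
#' `phylip_square` accepts both the square and the lower-triangle PHYLIP
#' layouts (one taxon per line). Asymmetries up to `1e-6` are averaged
#' away; anything larger, any negative entry, and any mismatch between the
#' declared taxon count and the rows found are errors.
#'
#' @param path input file.
#' @param dialect `"phylip_square"` or `"tsv"`.
#' @return an [evodist()].
#' @export
read_distance_matrix <- function(path, dialect = c("phylip_square", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) ps_stop("no such file: ", path)
  if (dialect == "tsv") {
    df <- read.delim(path, check.names = FALSE)
    labels <- as.character(df[[1]])
    d <- as.matrix(df[, -1, drop = FALSE])
    if (!identical(colnames(d), labels))
      ps_stop("tsv header labels do not match row labels")
    return(evodist(d, labels))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 2) ps_stop("bad taxon count header: '", lines[1], "'")
  body <- lines[-1]
  if (length(body) != n)
    ps_stop("header declares ", n, " taxa but file contains ",
            length(body), " rows")
  labels <- character(n)
  vals <- vector("list", n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(body[i]), "\\s+")[[1]]
    labels[i] <- tok[1]
    vals[[i]] <- suppressWarnings(as.numeric(tok[-1]))
    if (anyNA(vals[[i]]))
      ps_stop("non-numeric distance in row for '", labels[i], "'")
  }
  counts <- lengths(vals)
  if (all(counts == n)) {
    d <- do.call(rbind, vals)
  } else if (all(counts == seq_len(n) - 1)) {       # lower triangle
    d <- matrix(0, n, n)
    for (i in seq_len(n))
      if (i > 1) d[i, seq_len(i - 1)] <- vals[[i]]
    d <- d + t(d)
  } else {
    ps_stop("row lengths fit neither square nor lower-triangle layout")
  }
  evodist(d, labels)
}
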