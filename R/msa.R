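#' Construct a validated protein multiple sequence alignment
#'
#' An aligned set of amino-acid sequences is the object set of a sequence
#' space: each taxon is one point, each alignment column one (categorical)
#' dimension. Rows must be equal length, taxa unique, and every character
#' drawn from the 20 canonical amino acids, `X` (ambiguous) or `-` (gap).
#' `.` is accepted as a gap synonym and folded to `-`; lower case is folded
#' to upper. No other repair is ever applied.
#'
#' @param seqs named character vector of aligned rows (names are taxa), or
#'   an unnamed vector accompanied by `taxa`.
#' @param taxa optional character vector of taxon identifiers.
#' @return an object of class `protein_msa` with elements `taxa`, `seqs`
#'   (named, upper case) and `n_sites`.
#' @examples
#' msa <- protein_msa(c(A = "AAAA", B = "AATA"))
#' msa$n_sites
#' @export
protein_msa <- function(seqs, taxa = names(seqs)) {
  if (is.null(taxa)) ps_stop("taxon identifiers are required")
  taxa <- as.character(taxa)
  seqs <- toupper(as.character(seqs))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  if (length(seqs) == 0) ps_stop("alignment has no sequences")
  if (length(taxa) != length(seqs))
    ps_stop("got ", length(taxa), " taxa for ", length(seqs), " rows")
  if (any(!nzchar(taxa)) || anyNA(taxa))
    ps_stop("empty taxon identifier")
  if (anyDuplicated(taxa))
    ps_stop("duplicate taxon identifier: ",
            paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  bad_name <- grepl("[][\\s,:;()]", taxa, perl = TRUE)
  if (any(bad_name))
    ps_stop("taxon identifier contains whitespace or reserved characters: ",
            paste(taxa[bad_name], collapse = ", "))
  n_sites <- nchar(seqs[1])
  if (n_sites < 1) ps_stop("alignment has zero columns")
  ragged <- nchar(seqs) != n_sites
  if (any(ragged))
    ps_stop("alignment rows differ in length: taxon '", taxa[ragged][1],
            "' has ", nchar(seqs[ragged][1]), " columns, expected ", n_sites)
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    bad <- which(!(ch %in% MSA_ALPHABET))
    if (length(bad))
      ps_stop("illegal character '", ch[bad[1]], "' at position ", bad[1],
              " in taxon '", taxa[i], "'")
  }
  names(seqs) <- taxa
  structure(list(taxa = taxa, seqs = seqs, n_sites = n_sites),
            class = "protein_msa")
}

#' @export
print.protein_msa <- function(x, ...) {
  cat("protein_msa:", length(x$taxa), "taxa x", x$n_sites, "sites\n")
  show <- head(x$taxa, 6)
  for (t in show)
    cat(sprintf("  %-15s %s%s\n", t, substr(x$seqs[[t]], 1, 50),
                if (x$n_sites > 50) "..." else ""))
  if (length(x$taxa) > 6) cat("  ...\n")
  invisible(x)
}

#' @export
as.matrix.protein_msa <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$seqs, "", fixed = TRUE))
  rownames(m) <- x$taxa
  m
}

.sniff_msa_format <- function(path) {
  first <- ""
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    ln <- readLines(con, 1)
    if (!length(ln)) break
    if (nzchar(trimws(ln))) { first <- ln; break }
  }
  if (startsWith(trimws(first), ">")) return("fasta")
  if (grepl("^CLUSTAL", trimws(first), ignore.case = TRUE)) return("clustal")
  if (grepl("^\\s*[0-9]+\\s+[0-9]+\\s*$", first)) return("phylip")
  ps_stop("cannot detect alignment format of '", path, "'")
}

#' Read a protein alignment
#'
#' Supports FASTA, (strict or relaxed) PHYLIP and Clustal. Parsing of all
#' three formats is delegated to \code{seqinr::read.alignment}; the result
#' is then validated by [protein_msa()] (which never silently repairs
#' anything beyond the whitelisted case fold and `.`-to-`-` gap synonym).
#'
#' @param path file to read.
#' @param format one of `"auto"`, `"fasta"`, `"phylip"`, `"clustal"`.
#' @return a [protein_msa()].
#' @export
read_msa <- function(path, format = c("auto", "fasta", "phylip", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) ps_stop("no such file: ", path)
  if (format == "auto") format <- .sniff_msa_format(path)
  if (format == "clustal") return(.read_clustal(path))
  aln <- tryCatch(
    seqinr::read.alignment(path, format = format, forceToLower = FALSE),
    error = function(e) ps_stop("failed to parse '", path, "' as ", format,
                                ": ", conditionMessage(e)))
  protein_msa(unlist(aln$seq), trimws(aln$nam))
}

# Clustal reader: header line, then blocks of "name  chunk" rows with an
# optional conservation line (leading whitespace) under each block.
.read_clustal <- function(path) {
  lines <- readLines(path)
  if (!grepl("^CLUSTAL", trimws(lines[1]), ignore.case = TRUE))
    ps_stop("not a Clustal file (missing CLUSTAL header): ", path)
  lines <- lines[-1]
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^\\s", lines)]           # conservation rows
  m <- regmatches(lines, regexec("^(\\S+)\\s+(\\S+)\\s*\\d*$", lines))
  bad <- lengths(m) != 3
  if (any(bad)) ps_stop("malformed Clustal row: '", lines[bad][1], "'")
  nm <- vapply(m, `[`, "", 2)
  chunk <- vapply(m, `[`, "", 3)
  taxa <- unique(nm)
  seqs <- vapply(taxa, function(t)
    paste(chunk[nm == t], collapse = ""), character(1))
  protein_msa(seqs, taxa)
}

#' Write a protein alignment
#'
#' @param msa a [protein_msa()].
#' @param path output file.
#' @param format `"fasta"` (default, wrapped at 60 columns), `"phylip"`
#'   (sequential, relaxed names) or `"clustal"`.
#' @export
write_msa <- function(msa, path, format = c("fasta", "phylip", "clustal")) {
  format <- match.arg(format)
  stopifnot(inherits(msa, "protein_msa"))
  lines <- switch(format,
    fasta = unlist(lapply(msa$taxa, function(t) {
      s <- msa$seqs[[t]]
      c(paste0(">", t),
        substring(s, seq(1, nchar(s), 60), pmin(seq(60, nchar(s) + 59, 60), nchar(s))))
    })),
    phylip = c(paste(length(msa$taxa), msa$n_sites),
               sprintf("%-10s  %s", msa$taxa, msa$seqs)),
    clustal = {
      starts <- seq(1, msa$n_sites, 60)
      blocks <- lapply(starts, function(s) {
        chunk <- substr(msa$seqs, s, min(s + 59, msa$n_sites))
        # conservation line: '*' where the column is invariant
        cons <- paste(vapply(seq_len(nchar(chunk[1])), function(i) {
          col <- substr(chunk, i, i)
          if (length(unique(col)) == 1 && col[1] != "-") "*" else " "
        }, character(1)), collapse = "")
        c(sprintf("%-16s%s", msa$taxa, chunk),
          sprintf("%-16s%s", "", cons), "")
      })
      c("CLUSTAL W multiple sequence alignment", "", unlist(blocks))
    })
  writeLines(lines, path)
  invisible(path)
}
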