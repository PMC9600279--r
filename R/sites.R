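#' @importFrom methods is
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a collection of aligned binding sites
#'
#' A binding-site collection holds aligned, equal-length DNA sites used to
#' train the scoring matrix. CpxR sites are bipartite
#' (`GTAAA-N5-GTAAA`, 15 bp) or, after spacer expansion, 16 bp
#' (`GTAAA-N6-GTAAA`). Ambiguity codes are rejected: training sites must be
#' concrete sequences over A/C/G/T.
#'
#' @param sites character vector of DNA strings, all the same length.
#' @param labels optional per-site identifiers (recycled names allowed);
#'   defaults to `site1 ... siteN`.
#' @return An object of class `"cpx_sites"`: a character vector with
#'   attributes `site_length` and `labels`.
#' @examples
#' binding_sites(c("GTAAACCGCCGTAAA", "GTAAATTTTTGTAAA"))
#' @export
binding_sites <- function(sites, labels = NULL) {
  sites <- toupper(as.character(sites))
  if (length(sites) == 0L) {
    stop("binding-site collection must be non-empty")
  }
  lens <- nchar(sites)
  if (length(unique(lens)) != 1L) {
    stop("all sites must share one length; got lengths ",
         paste(sort(unique(lens)), collapse = ", "))
  }
  bad <- grepl("[^ACGT]", sites)
  if (any(bad)) {
    stop("non-ACGT character in site(s) ",
         paste(which(bad), collapse = ", "),
         " (ambiguity codes are not accepted in training sites)")
  }
  if (is.null(labels)) {
    labels <- paste0("site", seq_along(sites))
  }
  if (length(labels) != length(sites)) {
    stop("labels must match the number of sites")
  }
  structure(sites,
            site_length = lens[[1L]],
            labels = as.character(labels),
            class = "cpx_sites")
}

#' @export
print.cpx_sites <- function(x, ...) {
  cat(sprintf("Binding-site collection: %d sites x %d bp\n",
              length(x), attr(x, "site_length")))
  show <- utils::head(unclass(x), 5L)
  cat(paste0("  ", show, collapse = "\n"), "\n")
  if (length(x) > 5L) cat(sprintf("  ... and %d more\n", length(x) - 5L))
  invisible(x)
}

#' Read aligned binding sites from FASTA or plain text
#'
#' Accepts either a FASTA file (parsed with
#' [Biostrings::readDNAStringSet()]) or a plain text file with one site per
#' line (`#` comment lines and blank lines ignored).
#'
#' @param path file path.
#' @param format `"auto"` (sniff a leading `>`), `"fasta"` or `"lines"`.
#' @return A [binding_sites()] collection.
#' @export
read_binding_sites <- function(path, format = c("auto", "fasta", "lines")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (length(first) && startsWith(first, ">")) "fasta" else "lines"
  }
  if (format == "fasta") {
    ss <- Biostrings::readDNAStringSet(path)
    binding_sites(as.character(ss), labels = names(ss))
  } else {
    ln <- trimws(readLines(path))
    ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
    binding_sites(ln)
  }
}

#' Expand a 15-bp site to 16 bp by duplicating the middle spacer base
#'
#' Converts sites with a 5-bp spacer (`GTAAA-N5-GTAAA`, 15 bp) into the
#' 6-bp-spacer form (16 bp) by duplicating the middle base of the spacer,
#' i.e. the 8th base of the site. This compensates for the scarcity of
#' curated 16-bp sites: the 16-bp training set is derived from the 15-bp
#' one rather than collected independently.
#'
#' @param sites a character vector of 15-bp sites or a `"cpx_sites"`
#'   collection of 15-bp sites.
#' @return The expanded 16-bp sites, as a `"cpx_sites"` collection when the
#'   input was one, otherwise a character vector.
#' @examples
#' expand_spacer("GTAAACCGCCGTAAA")  # "GTAAACCGGCCGTAAA"
#' @export
expand_spacer <- function(sites) {
  was_coll <- inherits(sites, "cpx_sites")
  labels <- attr(sites, "labels")
  s <- toupper(as.character(sites))
  if (any(nchar(s) != 15L)) {
    stop("spacer expansion applies to 15-bp sites only")
  }
  if (any(grepl("[^ACGT]", s))) {
    stop("non-ACGT character in site")
  }
  out <- paste0(substr(s, 1L, 8L), substr(s, 8L, 8L), substr(s, 9L, 15L))
  if (was_coll) binding_sites(out, labels = labels) else out
}
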