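#' Generic residue numbering: label grammar
#'
#' Two schemes are supported. Ballesteros-Weinstein (BW) for class A
#' receptors: `<segment>.<index>` with segment in 1..8 (TM1-TM7, H8) or the
#' two-digit loop segments 12, 23, 34, 45, 56, 67, 78 (e.g. "3.54", "34.51").
#' Common Galpha numbering (CGN): `<segment>.<2-digit index>` with segments
#' such as HN, S1..S6, H1..H5 and joints like "h4s6" (e.g. "H5.20"); the
#' formal "G.H5.20" long form is accepted on input and emitted short.
#'
#' @param label character vector of labels.
#' @return normalized labels (short CGN form, uppercase segment).
#' @export
normalize_label <- function(label) {
  l <- trimws(as.character(label))
  l <- sub("^G\\.", "", l, ignore.case = TRUE)
  ifelse(grepl("^[0-9]", l), l, toupper(l))
}

bw_segments <- c("1" = "TM1", "2" = "TM2", "3" = "TM3", "4" = "TM4",
                 "5" = "TM5", "6" = "TM6", "7" = "TM7", "8" = "H8",
                 "12" = "ICL1", "23" = "ECL1", "34" = "ICL2",
                 "45" = "ECL2", "56" = "ICL3", "67" = "ECL3", "78" = "C78")

#' Validate a generic label against its scheme grammar
#' @param label label string(s).
#' @param scheme "BW" or "CGN".
#' @return logical vector.
#' @export
label_valid <- function(label, scheme = c("BW", "CGN")) {
  scheme <- match.arg(scheme)
  l <- normalize_label(label)
  if (scheme == "BW") {
    ok <- grepl("^(1|2|3|4|5|6|7|8|12|23|34|45|56|67|78)\\.[0-9]{1,2}$", l)
  } else {
    ok <- grepl("^(HN|HG|S[1-6]|H[1-5]|HNS1|S1H1|H1HA|HAHB|HBHC|HCHD|HDHE|HEHF|HFS2|S2S3|S3H2|H2S4|S4H3|H3S5|S5HG|S5H4|H4S6|S6H5)\\.[0-9]{2}$",
                l, ignore.case = TRUE)
  }
  ok
}

#' Segment of a generic label
#' @param label label string(s).
#' @param scheme "BW" or "CGN".
#' @return segment names ("TM3", "ICL2", "H5", ...).
#' @export
label_segment <- function(label, scheme = c("BW", "CGN")) {
  scheme <- match.arg(scheme)
  l <- normalize_label(label)
  seg <- sub("\\..*$", "", l)
  if (scheme == "BW") unname(bw_segments[seg]) else seg
}

#' Read a packaged (or user) generic-numbering reference table
#'
#' Reference tables are TSV with columns `generic_label`, `segment`,
#' `ref_seq_index`, `ref_aa` plus a `# sequence:` header line carrying the
#' full one-letter reference sequence. The tables shipped under
#' `inst/extdata` are synthetic stand-ins whose label/position anchors follow
#' published conventions for CB1-like and Galpha-like chains.
#'
#' @param name either a path to a TSV or one of the packaged table names
#'   "cb1_bw_synthetic", "gas_cgn_synthetic", "gai_cgn_synthetic".
#' @return list with `sequence` (character scalar) and `table` (data.frame).
#' @export
read_reference_table <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", paste0(name, ".tsv"), package = "gik")
  if (!nzchar(path) || !file.exists(path))
    stop("reference table not found: ", name)
  lines <- readLines(path)
  seq_line <- grep("^# sequence:", lines, value = TRUE)
  if (length(seq_line) != 1)
    stop("reference-table format error: missing '# sequence:' header in ", path)
  sequence <- trimws(sub("^# sequence:", "", seq_line))
  tab <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                           stringsAsFactors = FALSE)
  req <- c("generic_label", "segment", "ref_seq_index", "ref_aa")
  if (!all(req %in% names(tab)))
    stop("reference-table format error: need columns ",
         paste(req, collapse = ", "))
  if (anyDuplicated(tab$generic_label) || anyDuplicated(tab$ref_seq_index))
    stop("reference-table format error: labels and positions must be unique")
  chk <- substring(sequence, tab$ref_seq_index, tab$ref_seq_index)
  if (!all(chk == tab$ref_aa))
    stop("reference-table format error: ref_aa disagrees with sequence")
  list(sequence = sequence, table = tab, source = basename(path))
}

aa_3to1 <- function(resname) {
  out <- suppressWarnings(bio3d::aa321(resname))
  out[is.na(out) | out == "X"] <- "X"
  out
}

chain_sequence <- function(structure, chain) {
  rt <- residue_table(structure)
  rt <- rt[rt$chain == chain, , drop = FALSE]
  if (nrow(rt) == 0) stop("selection error: unknown chain ", chain)
  list(rt = rt, seq = paste(aa_3to1(rt$resname), collapse = ""))
}

#' Annotate a chain with generic labels by alignment to a reference table
#'
#' The chain sequence is globally aligned to the reference sequence
#' (BLOSUM62, affine gap 10/0.5). Labels are transferred only over aligned
#' (non-gap) columns; transfer over gaps never happens. The resulting map is
#' a bijection between residue keys and generic labels.
#'
#' @param structure a `gik_structure`.
#' @param chain chain id to annotate.
#' @param reference a table from [read_reference_table()] or a packaged name.
#' @param scheme "BW" or "CGN".
#' @param min_identity minimum fractional sequence identity over aligned
#'   columns; below this the chain is considered the wrong protein.
#' @return a `gik_numbering_map`: list with `chain`, `scheme`, `pairs`
#'   (data.frame chain, resnum, icode, resname, label, segment), `source`,
#'   `coverage` (mapped labels / reference labels), `identity`.
#' @export
annotate <- function(structure, chain, reference, scheme = c("BW", "CGN"),
                     min_identity = 0.9) {
  scheme <- match.arg(scheme)
  if (is.character(reference)) reference <- read_reference_table(reference)
  cs <- chain_sequence(structure, chain)
  ref_seq <- reference$sequence
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(cs$seq), Biostrings::AAString(ref_seq),
    substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 0.5,
    type = "global")
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  pc <- strsplit(p, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  aligned <- pc != "-" & sc != "-"
  ident <- sum(pc == sc & aligned) / sum(aligned)
  if (ident < min_identity)
    stop(sprintf("wrong-protein error: alignment identity %.3f below %.2f",
                 ident, min_identity))
  # column -> index in chain / reference
  ci <- cumsum(pc != "-"); ri <- cumsum(sc != "-")
  tab <- reference$table
  hit <- match(tab$ref_seq_index, ifelse(aligned, ri, NA))
  mapped <- !is.na(hit)
  chain_idx <- ci[hit[mapped]]
  rt <- cs$rt
  pairs <- data.frame(chain = rt$chain[chain_idx],
                      resnum = rt$resnum[chain_idx],
                      icode = rt$icode[chain_idx],
                      resname = rt$resname[chain_idx],
                      label = normalize_label(tab$generic_label[mapped]),
                      segment = tab$segment[mapped],
                      stringsAsFactors = FALSE)
  if (anyDuplicated(pairs$label) ||
      anyDuplicated(paste(pairs$chain, pairs$resnum, pairs$icode)))
    stop("annotation produced a non-bijective map")
  base::structure(list(chain = chain, scheme = scheme, pairs = pairs,
                 source = reference$source,
                 coverage = nrow(pairs) / nrow(tab), identity = ident),
            class = "gik_numbering_map")
}

blosum62 <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      mat <<- get("BLOSUM62", envir = e)
    }
    mat
  }
})

#' Build a numbering map directly from explicit residue/label pairs
#'
#' Used by the synthetic generators, where the mapping is known by
#' construction rather than inferred by alignment.
#'
#' @param chain chain id.
#' @param scheme "BW" or "CGN".
#' @param resnum integer residue numbers.
#' @param label generic labels (same length).
#' @param resname residue names (recycled).
#' @param icode insertion codes (recycled).
#' @param source provenance string.
#' @return a `gik_numbering_map`.
#' @export
numbering_map <- function(chain, scheme, resnum, label,
                          resname = "ALA", icode = "", source = "synthetic") {
  label <- normalize_label(label)
  if (length(resnum) != length(label)) stop("resnum/label length mismatch")
  if (anyDuplicated(label) || anyDuplicated(paste(resnum, icode)))
    stop("numbering map must be a bijection")
  bad <- !label_valid(label, scheme)
  if (any(bad)) stop("label(s) violate ", scheme, " grammar: ",
                     paste(label[bad], collapse = ", "))
  pairs <- data.frame(chain = chain, resnum = as.integer(resnum),
                      icode = rep_len(icode, length(resnum)),
                      resname = rep_len(resname, length(resnum)),
                      label = label,
                      segment = label_segment(label, scheme),
                      stringsAsFactors = FALSE)
  structure(list(chain = chain, scheme = scheme, pairs = pairs,
                 source = source, coverage = 1, identity = 1),
            class = "gik_numbering_map")
}

#' @export
print.gik_numbering_map <- function(x, ...) {
  cat(sprintf("<gik_numbering_map chain %s, %s, %d labels, coverage %.2f, source %s>\n",
              x$chain, x$scheme, nrow(x$pairs), x$coverage, x$source))
  invisible(x)
}

#' Translate a residue key to its generic label
#' @param map a `gik_numbering_map`.
#' @param resnum author residue number.
#' @param icode insertion code.
#' @return label string.
#' @export
to_generic <- function(map, resnum, icode = "") {
  i <- which(map$pairs$resnum == resnum & map$pairs$icode == icode)
  if (length(i) != 1)
    stop("lookup error: residue ", resnum, icode, " not in map for chain ",
         map$chain)
  map$pairs$label[i]
}

#' Translate a generic label to its residue key
#' @param map a `gik_numbering_map`.
#' @param label generic label (long CGN form accepted).
#' @return one-row data.frame (chain, resnum, icode, resname, label, segment).
#' @export
to_residue <- function(map, label) {
  label <- normalize_label(label)
  i <- which(map$pairs$label == label)
  if (length(i) != 1)
    stop("lookup error: label ", label, " not in map for chain ", map$chain)
  map$pairs[i, , drop = FALSE]
}
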