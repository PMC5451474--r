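## Seed-based miRNA target prediction.  The seed is nucleotides 2-8 of the
## mature miRNA (5'->3'); a target site is an exact Watson-Crick match of the
## seed's DNA reverse complement on the 3'-UTR sense strand.

normalize_rna <- function(s) {
  s <- chartr("tu", "TU", toupper(s))
  chartr("T", "U", s)
}

normalize_dna <- function(s) {
  s <- toupper(s)
  chartr("U", "T", s)
}

#' Extract the seed (positions 2-8) of a mature miRNA
#'
#' Normalizes the input to the RNA alphabet and returns the 7-nt substring at
#' 1-based positions 2-8 from the 5' end.
#'
#' @param mirna mature miRNA sequence, length >= 8 nt; RNA or DNA alphabet,
#'   any case.
#' @return 7-character RNA seed string.
#' @examples
#' extract_seed("UAGCUUAUCAGACUGAUGUUGA")  # "AGCUUAU"
#' @export
extract_seed <- function(mirna) {
  s <- normalize_rna(mirna)
  if (nchar(s) < 8) stop("miRNA sequence shorter than 8 nt")
  if (grepl("[^ACGU]", s)) stop("miRNA sequence contains non-ACGU characters")
  substr(s, 2, 8)
}

#' DNA motif matched by a seed on the UTR sense strand
#'
#' The reverse complement, in the DNA alphabet, of a 7-nt RNA seed.
#'
#' @param seed 7-nt RNA seed (from [extract_seed()]).
#' @return 7-character DNA motif.
#' @export
seed_site_motif <- function(seed) {
  s <- normalize_dna(seed)
  if (nchar(s) != 7) stop("seed must be exactly 7 nt")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Scan a 3'-UTR for seed-complement sites
#'
#' Finds every (possibly overlapping) exact occurrence of the seed's DNA
#' reverse complement on the UTR sense strand.  Input case and U/T encoding
#' are normalized; sites overlapping an `N` are skipped; other non-ACGTN
#' characters are rejected.
#'
#' @param seed 7-nt RNA seed.
#' @param utr UTR sequence (DNA or RNA alphabet, any case).
#' @return data.frame with columns `start`, `end` (1-based inclusive, sense
#'   strand) and `motif`; zero rows when there is no site.
#' @export
scan_utr <- function(seed, utr) {
  utr <- normalize_dna(as.character(utr))
  if (grepl("[^ACGTN]", utr)) stop("UTR contains non-ACGTN characters")
  if (nchar(utr) < 7) stop("UTR shorter than 7 nt")
  motif <- seed_site_motif(seed)
  hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(utr),
                                   fixed = TRUE)
  st <- Biostrings::start(hits)
  data.frame(start = st, end = st + 6L,
             motif = rep(motif, length(st)),
             stringsAsFactors = FALSE)
}

#' Predict miRNA targets over a set of 3'-UTRs
#'
#' Scans every UTR for the seed-complement motif of every miRNA and reports
#' unique (miRNA, gene) pairs with their site counts and positions.
#'
#' @param mirnas named character vector of mature miRNA sequences, or a
#'   FASTA path readable by [Biostrings::readRNAStringSet].
#' @param utrs named character vector / [Biostrings::DNAStringSet] of
#'   3'-UTRs, or a FASTA path.
#' @param restrict_to optional gene-id set; pairs for other genes are dropped
#'   (e.g. to restrict to the expressed-gene universe).
#' @return data.frame with columns `mirna_id`, `gene_id`, `n_sites`,
#'   `positions` (comma-separated 1-based starts).
#' @export
predict_targets <- function(mirnas, utrs, restrict_to = NULL) {
  if (is.character(mirnas) && length(mirnas) == 1 && file.exists(mirnas))
    mirnas <- as.character(Biostrings::readRNAStringSet(mirnas))
  if (is.character(utrs) && length(utrs) == 1 && file.exists(utrs))
    utrs <- Biostrings::readDNAStringSet(utrs)
  utrs <- vapply(as.character(utrs), identity, "")
  if (length(mirnas) == 0 || length(utrs) == 0)
    stop("miRNA and UTR inputs must be non-empty")
  if (anyDuplicated(names(utrs))) stop("duplicate UTR (gene) identifiers")
  if (anyDuplicated(names(mirnas))) stop("duplicate miRNA identifiers")
  if (!is.null(restrict_to)) utrs <- utrs[names(utrs) %in% restrict_to]
  rows <- list()
  for (m in names(mirnas)) {
    seed <- extract_seed(mirnas[[m]])
    for (g in names(utrs)) {
      sites <- scan_utr(seed, utrs[[g]])
      if (nrow(sites) > 0)
        rows[[length(rows) + 1]] <- data.frame(
          mirna_id = m, gene_id = g, n_sites = nrow(sites),
          positions = paste(sites$start, collapse = ","),
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(mirna_id = character(), gene_id = character(),
                      n_sites = integer(), positions = character()))
  out <- do.call(rbind, rows)
  out[order(out$mirna_id, out$gene_id), , drop = FALSE]
}
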