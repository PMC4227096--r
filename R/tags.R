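#' Build the 18-bp tag library for a genome's CCGG sites
#'
#' MSCC sequencing reads are 18-bp tags released adjacent to the HpaII cut at
#' `C^CGG`. For a CCGG whose first C is at 0-based position `p`, the
#' plus-strand tag is the 18 bases starting at `p+1`, and the minus-strand tag
#' is the reverse complement of the 18 bases at positions `p-15 .. p+2`. Tags
#' whose 18-mer occurs at more than one (site, strand) location are moved to
#' the ambiguous set and never counted. Sites too close to a contig end
#' contribute no tag for the truncated side.
#'
#' @param genome an `mscc_genome` object.
#' @return list of class `tag_library`: `entries` data.frame (`tag`,
#'   `site_id`, `strand`) with unique tags only, and `ambiguous_tags`
#'   character vector.
#' @export
build_tag_library <- function(genome) {
  sites <- genome$ccgg_sites
  out <- list()
  for (ch in names(genome$sequences)) {
    s <- genome$sequences[[ch]]
    len <- nchar(s)
    sub <- sites[sites$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0) next
    p <- sub$pos
    ok_plus <- p + 19L <= len          # 0-based p+1 .. p+18 within sequence
    ok_minus <- p >= 15L               # 0-based p-15 .. p+2 within sequence
    if (any(ok_plus)) {
      out[[length(out) + 1L]] <- data.frame(
        tag = substring(s, p[ok_plus] + 2L, p[ok_plus] + 19L),
        site_id = sub$site_id[ok_plus], strand = "+",
        stringsAsFactors = FALSE)
    }
    if (any(ok_minus)) {
      fwd <- substring(s, p[ok_minus] - 14L, p[ok_minus] + 3L)
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(fwd)))
      out[[length(out) + 1L]] <- data.frame(
        tag = rc, site_id = sub$site_id[ok_minus], strand = "-",
        stringsAsFactors = FALSE)
    }
  }
  entries <- if (length(out)) do.call(rbind, out) else
    data.frame(tag = character(0), site_id = character(0),
               strand = character(0), stringsAsFactors = FALSE)
  dup <- unique(entries$tag[duplicated(entries$tag)])
  amb <- entries$tag %in% dup
  structure(list(entries = entries[!amb, , drop = FALSE],
                 ambiguous_tags = dup),
            class = "tag_library")
}

#' Count tag reads against a tag library
#'
#' A read is assigned to a site iff its first 18 bases exactly equal one of
#' the library's unique tags; reads matching an ambiguous tag are discarded
#' (tallied), everything else is unmatched. Reads shorter than 18 bases are
#' unmatched with a warning.
#'
#' @param reads a character vector, a `Biostrings::DNAStringSet`, or the path
#'   to a FASTQ file.
#' @param library a `tag_library` object.
#' @return list: `counts` data.frame (`site_id`, `count`; zero rows for
#'   unobserved sites included), `n_assigned`, `n_ambiguous`, `n_unmatched`.
#' @export
count_tags <- function(reads, library) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
  reads <- as.character(reads)
  short <- nchar(reads) < 18L
  if (any(short))
    warning(sprintf("%d reads shorter than 18 bases counted as unmatched",
                    sum(short)))
  prefix <- substr(reads[!short], 1L, 18L)
  hit <- match(prefix, library$entries$tag)
  amb <- is.na(hit) & prefix %in% library$ambiguous_tags
  assigned <- library$entries$site_id[hit[!is.na(hit)]]
  tab <- table(assigned)
  all_sites <- unique(library$entries$site_id)
  counts <- data.frame(site_id = all_sites,
                       count = as.integer(tab[all_sites]),
                       stringsAsFactors = FALSE)
  counts$count[is.na(counts$count)] <- 0L
  list(counts = counts,
       n_assigned = sum(!is.na(hit)),
       n_ambiguous = sum(amb),
       n_unmatched = sum(is.na(hit) & !amb) + sum(short))
}

#' Write simulated tag reads as FASTQ
#'
#' Expands a per-site count table into raw 18-bp tag reads (picking each
#' site's available strand tags uniformly at random) and writes them as a
#' FASTQ file with constant qualities. This is the generator's raw-read mode,
#' used to exercise the read-level counting path.
#'
#' @param counts data.frame (`site_id`, `count`).
#' @param library a `tag_library` object.
#' @param path output FASTQ path.
#' @param seed RNG seed for strand choice.
#' @return invisibly, the number of reads written.
#' @export
write_tag_fastq <- function(counts, library, path, seed = 1L) {
  entries <- library$entries
  withr::with_seed(seed, {
    reads <- character(0)
    for (i in seq_len(nrow(counts))) {
      k <- counts$count[i]
      if (k <= 0) next
      tags <- entries$tag[entries$site_id == counts$site_id[i]]
      if (length(tags) == 0) next
      reads <- c(reads, sample(tags, k, replace = TRUE))
    }
    dna <- Biostrings::DNAStringSet(reads)
    if (length(dna))
      names(dna) <- sprintf("read%06d", seq_along(dna))
    qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(dna)))
    Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
    invisible(length(dna))
  })
}
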