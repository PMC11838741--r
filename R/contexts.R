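# SBS96 channel definitions and substitution classification.
#
# Channels follow the COSMIC convention: six pyrimidine-standardized
# substitutions (C>A, C>G, C>T, T>A, T>C, T>G), each in 16 trinucleotide
# contexts ordered by upstream then downstream base (A, C, G, T).

SBS_SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
BASES <- c("A", "C", "G", "T")

#' SBS96 channel labels
#'
#' @return Character vector of the 96 channel labels in COSMIC order,
#'   e.g. `"A[C>A]A"`.
#' @export
sbs96_channels <- function() {
  unlist(lapply(SBS_SUBSTITUTIONS, function(s) {
    as.vector(t(outer(BASES, BASES, function(u, d) paste0(u, "[", s, "]", d))))
  }))
}

#' The 32 pyrimidine-centred trinucleotide context classes
#'
#' Positional contexts (central base C or T) that constrain where a mutation
#' of a given channel can be placed or permuted to.
#'
#' @return Character vector of 32 trinucleotides such as `"ACA"`.
#' @export
pyrimidine_contexts <- function() {
  unlist(lapply(c("C", "T"), function(m) {
    as.vector(t(outer(BASES, BASES, function(u, d) paste0(u, m, d))))
  }))
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, ""), function(b) {
    paste(rev(b), collapse = "")
  }, character(1)))
}

comp_base <- function(x) chartr("ACGT", "TGCA", x)

#' Classify a base substitution into its SBS96 channel
#'
#' Purine-reference substitutions are reverse-complemented to the pyrimidine
#' standard. For C>T substitutions, CpG status is read from the standardized
#' downstream base.
#'
#' @param ref,alt Reference and alternate bases (vectors of "A"/"C"/"G"/"T").
#' @param upstream,downstream Flanking reference bases on the forward strand.
#' @return A tibble with columns `channel` (e.g. `"A[C>A]A"`), `channel_index`
#'   (1-96), `substitution` (pyrimidine-standardized, e.g. `"C>A"`) and
#'   `class` (seven-way class separating `"C>T at CpG"` from
#'   `"C>T at non-CpG"`).
#' @export
classify_substitution <- function(ref, alt, upstream, downstream) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(upstream) == n, length(downstream) == n)
  ok <- c(ref, alt, upstream, downstream) %in% BASES
  if (!all(ok)) {
    abort("classify_substitution(): bases must be A/C/G/T (no ambiguity codes)")
  }
  if (any(ref == alt)) abort("classify_substitution(): ref and alt must differ")

  is_pur <- ref %in% c("A", "G")
  s_ref <- ifelse(is_pur, comp_base(ref), ref)
  s_alt <- ifelse(is_pur, comp_base(alt), alt)
  s_up <- ifelse(is_pur, comp_base(downstream), upstream)
  s_down <- ifelse(is_pur, comp_base(upstream), downstream)

  channel <- paste0(s_up, "[", s_ref, ">", s_alt, "]", s_down)
  idx <- match(channel, sbs96_channels())
  substitution <- paste0(s_ref, ">", s_alt)
  class <- substitution
  ctg <- substitution == "C>T"
  class[ctg & s_down == "G"] <- "C>T at CpG"
  class[ctg & s_down != "G"] <- "C>T at non-CpG"

  tibble::tibble(
    channel = channel, channel_index = idx,
    substitution = substitution, class = class
  )
}

#' Pyrimidine-standardized positional context for reference positions
#'
#' @param sequence Reference sequence as a single character string.
#' @param pos 1-based positions (must have both flanks on the contig).
#' @return Character vector of 32-class contexts (central base C or T).
#' @export
pyr_context_at <- function(sequence, pos) {
  len <- nchar(sequence)
  if (any(pos < 2L | pos > len - 1L)) {
    abort("pyr_context_at(): positions must have both flanking bases")
  }
  tri <- substring(sequence, pos - 1L, pos + 1L)
  mid <- substring(sequence, pos, pos)
  pur <- mid %in% c("A", "G")
  if (any(pur)) tri[pur] <- revcomp(tri[pur])
  tri
}

# Positional context class (32-way) for each SBS96 channel.
channel_context <- function(channel) {
  paste0(substr(channel, 1, 1), substr(channel, 3, 3), substr(channel, 7, 7))
}
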