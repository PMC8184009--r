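# Shared coordinate and key helpers.
#
# All internal coordinates are 0-based half-open. A "boundary" b is the cut
# point between genomic base b-1 and base b on the plus strand. Junctions are
# stored as the intron interval [start, end) with a strand; the donor boundary
# is the transcription-5' end of the intron (start on "+", end on "-") and the
# acceptor boundary the transcription-3' end (end on "+", start on "-").

junction_key <- function(chrom, strand, start, end) {
  paste(chrom, strand, start, end, sep = ":")
}

site_key <- function(chrom, strand, pos) {
  paste(chrom, strand, pos, sep = ":")
}

donor_boundary <- function(strand, start, end) {
  ifelse(strand == "+", start, end)
}

acceptor_boundary <- function(strand, start, end) {
  ifelse(strand == "+", end, start)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @keywords internal
log_kv <- function(stage, ...) {
  kv <- list(...)
  msg <- paste0("stage=", stage)
  if (length(kv)) {
    msg <- paste(msg, paste(names(kv), unlist(kv), sep = "=", collapse = " "))
  }
  message(msg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rbind a list of data.frames, ignoring NULLs; NULL when nothing to bind
rbind_all <- function(lst) {
  lst <- Filter(Negate(is.null), lst)
  if (!length(lst)) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}
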