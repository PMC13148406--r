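# FASTA plumbing (Biostrings-backed). Sequences travel internally as plain
# named character vectors; XStringSet objects only exist at the file border.

read_fasta_vector <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- tryCatch(
    if (type == "AA") Biostrings::readAAStringSet(path)
    else Biostrings::readDNAStringSet(path),
    error = function(e) stop(sprintf("cannot read FASTA '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  out <- as.character(set)
  # keep only the id token of each description line
  names(out) <- sub("\\s.*$", "", names(out))
  if (anyDuplicated(names(out)))
    stop(sprintf("duplicate sequence ids in '%s'", path), call. = FALSE)
  out
}

write_fasta_vector <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::AAStringSet(seqs)
    else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}
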