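# Tiny hand-built genome/annotation fixtures written at test time.

write_fasta <- function(records, path) {
  lines <- unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]])))
  writeLines(lines, path)
  path
}

# GFF3 writer for hand-specified features:
# feats is a data.frame with seqid, type, start, end, strand, id, parent
write_gff3 <- function(feats, path) {
  attrs <- ifelse(is.na(feats$parent) | feats$parent == "",
                  paste0("ID=", feats$id),
                  paste0("ID=", feats$id, ";Parent=", feats$parent))
  lines <- c("##gff-version 3",
             paste(feats$seqid, "test", feats$type, feats$start, feats$end,
                   ".", feats$strand, ifelse(feats$type == "CDS", "0", "."),
                   attrs, sep = "\t"))
  writeLines(lines, path)
  path
}

feat_row <- function(seqid, type, start, end, strand, id, parent = NA) {
  data.frame(seqid = seqid, type = type, start = start, end = end,
             strand = strand, id = id, parent = parent,
             stringsAsFactors = FALSE)
}
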