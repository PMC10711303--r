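# small in-code fixtures shared across test files

amoebozoa_lineage <- "cellular organisms;Eukaryota;Amoebozoa;Archamoebae"
bacteria_lineage <- "cellular organisms;Bacteria;Pseudomonadota"

# one-line outfmt6_tax row builder
hit_row <- function(qseqid, sseqid = "s1", pident = 80, qcovs = 60,
                    evalue = 1e-20, bitscore = 200,
                    lineage = bacteria_lineage) {
  data.frame(qseqid = qseqid, sseqid = sseqid, pident = pident, length = 100L,
             mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 100L,
             sstart = 1L, send = 100L, evalue = evalue, bitscore = bitscore,
             qcovs = qcovs, lineage = lineage, stringsAsFactors = FALSE)
}

hits_of <- function(...) do.call(rbind, list(...))

# normalized-call table builder: one row per (tool, protein)
call_row <- function(tool, protein_id, normalized_class) {
  data.frame(tool_name = tool, protein_id = protein_id, raw_class = "x",
             normalized_class = normalized_class, score = NA_real_,
             stringsAsFactors = FALSE)
}
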