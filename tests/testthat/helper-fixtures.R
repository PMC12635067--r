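# Shared builders and independent oracles for the test suite.

flat_layout <- function(len = 1e6, gaps = NULL) {
  contigs <- data.frame(name = "chr1", length = as.integer(len))
  if (is.null(gaps)) genome_layout(contigs) else genome_layout(contigs, gaps)
}

te_row <- function(id, start, end, family, subfamily, divergence = 5,
                   contig = "chr1", strand = "+") {
  data.frame(element_id = id, contig = contig, start = as.integer(start),
             end = as.integer(end), strand = strand, family = family,
             subfamily = subfamily, divergence = divergence,
             stringsAsFactors = FALSE)
}

del_call <- function(id, start, end, contig = "chr1", support = 10L,
                     depth = 20L, genotype = "0/1", vaf = 0.5,
                     sample_id = "s1") {
  sv_calls(call_id = id, contig = contig, start = as.integer(start),
           end = as.integer(end), svtype = "DEL",
           length = as.integer(end - start), support = support,
           depth = depth, filter = "PASS", genotype = genotype, gq = 40L,
           vaf = vaf, sample_id = sample_id)
}

ins_call <- function(id, start, length, contig = "chr1", support = 10L,
                     depth = 20L, genotype = "0/1", vaf = 0.5,
                     sample_id = "s1", sequence = NA_character_) {
  sv_calls(call_id = id, contig = contig, start = as.integer(start),
           end = as.integer(start), svtype = "INS",
           length = as.integer(length), sequence = sequence,
           support = support, depth = depth, filter = "PASS",
           genotype = genotype, gq = 40L, vaf = vaf, sample_id = sample_id)
}

full_track <- function(len = 1e6, depth = 30L, contig = "chr1") {
  data.frame(contig = contig, start = 0L, end = as.integer(len),
             depth = as.integer(depth))
}

# Independent NAHR oracle: brute-force enumeration of all ordered element
# pairs; a deletion is NAHR-consistent iff some pair of DISTINCT elements
# of one family overlaps (left breakpoint, right breakpoint) respectively,
# with each element expanded by `window`.
brute_force_nahr <- function(deletion, elements, window) {
  n <- nrow(elements)
  pairs <- expand.grid(i = seq_len(n), j = seq_len(n))
  pairs <- pairs[pairs$i != pairs$j, ]
  i <- pairs$i; j <- pairs$j
  hits_bp <- function(k, bp) {
    elements$contig[k] == deletion$contig &
      elements$start[k] - window <= bp & bp < elements$end[k] + window
  }
  any(elements$family[i] == elements$family[j] &
        hits_bp(i, deletion$start) & hits_bp(j, deletion$end))
}

random_nahr_instance <- function(seed, n_elements = 60L, n_deletions = 15L,
                                 span = 2e5) {
  set.seed(seed)
  start <- sort(sample.int(span - 500L, n_elements))
  len <- sample(80:400, n_elements, replace = TRUE)
  fam <- sample(c("SINE/Alu", "LINE/L1"), n_elements, replace = TRUE)
  elements <- data.frame(
    element_id = sprintf("E%03d", seq_len(n_elements)), contig = "chr1",
    start = start, end = start + len, strand = "+", family = fam,
    subfamily = ifelse(fam == "SINE/Alu", "AluY", "L1PA2"),
    divergence = round(runif(n_elements, 0, 20), 1),
    stringsAsFactors = FALSE)
  ds <- sample.int(span - 5000L, n_deletions)
  dlen <- sample(200:4000, n_deletions, replace = TRUE)
  deletions <- sv_calls(call_id = sprintf("D%03d", seq_len(n_deletions)),
                        contig = "chr1", start = ds, end = ds + dlen,
                        svtype = "DEL", length = dlen, support = 10L,
                        depth = 20L, filter = "PASS", genotype = "0/1",
                        sample_id = "s1")
  list(elements = elements, deletions = deletions)
}
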