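# Shared desk-scale fixtures: a 6-node tree with an outgroup clade and the
# 6-sample cohort (s1,s2 outgroup; s3,s4 O1a; s5 O1b; s6 O2) used across the
# screen tests.

toy_markers <- function() {
  data.frame(
    name = c("mO", "mO1", "mO1a", "mO1b", "mO2", "mN"),
    haplogroup = c("O", "O1", "O1a", "O1b", "O2", "N"),
    position = c(1000L, 2000L, 3000L, 4000L, 5000L, 6000L),
    ancestral = c("A", "C", "G", "T", "A", "C"),
    derived = c("G", "T", "A", "C", "T", "A"),
    stringsAsFactors = FALSE)
}

toy_tree <- function(markers = toy_markers()) {
  parse_haplogroup_tree("(((O1a,O1b)O1,O2)O,N)Y;", markers)
}

toy_calls <- function() {
  data.frame(sample = paste0("s", 1:6),
             haplogroup = c("N", "N", "O1a", "O1a", "O1b", "O2"),
             stringsAsFactors = FALSE)
}

# build a geno_matrix directly from a 0/1/NA matrix (rows named by
# "pos:ref:alt" shorthand), bypassing VCF I/O
make_gm <- function(calls, pos, ref, alt, id = NA_character_) {
  samples <- colnames(calls)
  id <- rep_len(id, nrow(calls))
  variants <- data.frame(
    key = paste("chrY", pos, ref, alt, sep = ":"),
    chrom = "chrY", pos = as.integer(pos), id = id, ref = ref, alt = alt,
    class = ifelse(nchar(ref) != nchar(alt), "biallelic_indel",
                   ifelse(nchar(ref) == 1, "snp", "mnp")),
    stringsAsFactors = FALSE)
  m <- matrix(as.integer(calls), nrow = nrow(calls),
              dimnames = list(variants$key, samples))
  structure(list(variants = variants, samples = samples, calls = m),
            class = "geno_matrix")
}

# swap REF/ALT encodings of every variant and flip the 0/1 codes
flip_gm <- function(gm) {
  v <- gm$variants
  new_v <- data.frame(key = paste(v$chrom, v$pos, v$alt, v$ref, sep = ":"),
                      chrom = v$chrom, pos = v$pos, id = v$id,
                      ref = v$alt, alt = v$ref, class = v$class,
                      stringsAsFactors = FALSE)
  m <- 1L - gm$calls
  rownames(m) <- new_v$key
  structure(list(variants = new_v, samples = gm$samples, calls = m),
            class = "geno_matrix")
}

# run the screen directly on a simulated cohort (in-memory path)
screen_sim <- function(sim, min_call_fraction = 0.9, strict_missing = FALSE) {
  run_screen(sim$vt, sim$tree, known = sim$known, focal = sim$config$focal,
             min_call_fraction = min_call_fraction,
             strict_missing = strict_missing)
}

quietly <- function(expr) suppressMessages(suppressWarnings(expr))
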