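# Shared fixtures, built in code at test time.

tiny_panel <- function(n_cpgs = 120, k_sig = 5, seed = 11) {
  make_reference_panel(n_cpgs, wb_celltypes(), k_sig, seed = seed)
}

tiny_cohort <- function(n_ns = 15, n_sm = 15, seed = 12) {
  make_cohort(n_ns, n_sm, seed = seed)
}

# deterministic hand-built panel: 3 CpGs x 3 types, full rank
hand_panel <- function() {
  prof <- matrix(c(0.9, 0.1, 0.1,
                   0.1, 0.9, 0.1,
                   0.1, 0.1, 0.9), nrow = 3, byrow = FALSE,
                 dimnames = list(c("cg1", "cg2", "cg3"),
                                 c("A", "B", "C")))
  structure(list(profiles = prof,
                 signature = list(A = "cg1", B = "cg2", C = "cg3"),
                 annot = data.frame(cpg_id = c("cg1", "cg2", "cg3"),
                                    chrom = "chrS", pos = c(10L, 20L, 30L),
                                    stringsAsFactors = FALSE)),
            class = "ref_panel")
}

minimal_vcf_lines <- function() {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=chrS>",
    paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
           "Description=\"Genotype\">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "chrS\t101\trs1\tA\tG\t.\tPASS\t.\tGT\t0/1\t1|1\t0/0",
    "chrS\t201\trs2\tC\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1")
}
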