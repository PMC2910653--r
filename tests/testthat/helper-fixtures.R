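# Small constructed inputs shared across tests.

# a 3-row RepeatMasker .out: one plus hit, one C (minus) hit, one starred hit
rm_three_rows <- function() {
  c("   SW   perc perc perc  query  position in query  matching repeat  position in repeat",
    "score   div. del. ins.  sequence begin end (left)  repeat class/family begin end (left) ID",
    "",
    "  463  1.3  0.5  0.0  seq1  1000  1199 (500)  +  MIR3    SINE/MIR   1 200 (200)  1",
    "  310  2.1  0.5  0.0  seq1  1250  1450 (300)  C  WSINE1  SINE/tRNA  (0) 201 1    2",
    "  463  1.9  0.5  0.0  seq1  1500  1699 (100)  +  MIR3    SINE/MIR   201 400 (0)  3 *")
}

# annotation with a host split by a guest (the minimal clean TinT layout);
# consensus coordinates of the host are continuous across the guest
nested_annotation <- function(host_cons = list(c(1, 200), c(201, 400)),
                              strand = "+", guest_family = "WSINE1") {
  repeat_annotation(tibble::tibble(
    sequence_id = "seq1",
    genome_start = c(1000, 1250, 1500),
    genome_end = c(1199, 1450, 1699),
    strand = c(strand, "+", strand),
    family = c("MIR3", guest_family, "MIR3"),
    repeat_class = c("SINE/MIR", "SINE/tRNA", "SINE/MIR"),
    consensus_start = c(host_cons[[1]][1], 1, host_cons[[2]][1]),
    consensus_end = c(host_cons[[1]][2], 200, host_cons[[2]][2])),
    source_label = "toy")
}

toy_sim_config <- function(seed = 11, ils_rate = 0, missing_rate = 0,
                           deletion_rate = 0, rate = 120) {
  tr <- read_newick(text = "((A:1,B:1):1,(C:1.5,D:0.5):0.5):0;")
  fam <- data.frame(name = c("OLD1", "MID1", "YNG1"),
                    mu = c(0.3, 1.0, 1.7), sigma = rep(0.25, 3),
                    rate = rep(rate, 3), length = c(300, 250, 200))
  sim_config(tr, fam, genome_length = 2e5, seed = seed, ils_rate = ils_rate,
             missing_rate = missing_rate, deletion_rate = deletion_rate)
}

# 8-ingroup-taxon tree with enough insertions that every internal edge gets
# several markers; used for end-to-end recovery
recovery_sim_config <- function(seed = 21) {
  tr <- read_newick(text = paste0(
    "(((A:0.5,B:0.5):0.5,(C:0.4,D:0.6):0.5):0.5,",
    "((E:0.6,F:0.4):0.6,(G:0.3,H:0.7):0.4):0.5):0;"))
  fam <- data.frame(name = c("F1", "F2"), mu = c(0.6, 1.2),
                    sigma = c(0.5, 0.5), rate = c(120, 120),
                    length = c(200, 200))
  sim_config(tr, fam, genome_length = 5e5, seed = seed)
}
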