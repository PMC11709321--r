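# Shared fixtures: everything is generated in code at test time.

# small 3-leaf rooted tree with fixed branch lengths
tiny_tree <- function() {
  ape::read.tree(text = "((a:0.1,b:0.2):0.15,c:0.3);")
}

# a random but reproducible fitness vector
random_F <- function(seed = 1, sd = 2) {
  set.seed(seed)
  gauge_normalize(rnorm(20, 0, sd))
}

# matrix exponential oracle for transition probabilities
expm_oracle <- function(Q, t) as.matrix(Matrix::expm(Q * t))

# extract outgroup nucleotide states at SNP positions from a phylo-mode
# bundle, in the layout polarize() consumes
snp_outgroup_states <- function(bundle) {
  gc <- genetic_code()
  snps <- bundle$snps
  a <- codon_index(snps$ancestral_codon)
  d <- codon_index(snps$derived_codon)
  pos <- apply(gc$codon_base[a, , drop = FALSE] !=
                 gc$codon_base[d, , drop = FALSE], 1, which)
  outs <- setdiff(rownames(bundle$alignment), bundle$scenario$focal)
  ob <- sapply(outs, function(o) {
    oc <- unclass(bundle$alignment)[o, snps$site + 1]
    ifelse(is.na(oc), "N", substr(gc$codons[oc], pos, pos))
  })
  list(alleles = cbind(substring(snps$ancestral_codon, pos, pos),
                       substring(snps$derived_codon, pos, pos)),
       outgroups = ob,
       counts = cbind(snps$n - snps$derived_count, snps$derived_count))
}

# classify the event log of simulate_alignment() by S0
classify_events <- function(events, profiles) {
  gc <- genetic_code()
  aaf <- gc$aa_index[events$from]
  aat <- gc$aa_index[events$to]
  syn <- aaf == aat
  S0 <- ifelse(syn, 0,
               profiles[cbind(events$site, aat)] -
                 profiles[cbind(events$site, aaf)])
  classify_s0(S0, syn)
}
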