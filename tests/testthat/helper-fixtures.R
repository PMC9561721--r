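# Fixture builders shared across test files. Everything is generated in code;
# no binary fixtures.

make_signed <- function(genes, scores, id = "fix") {
  signed_scores(genes, scores, study_id = id)
}

# A signature over genes g1..gN with sign1 decreasing from +N/2 to -N/2
# (no zeros), handy for RRHO and top-list tests.
ladder_signature <- function(N, id = "ladder") {
  s <- seq(N / 2, -N / 2, length.out = N)
  s[s == 0] <- 1e-6
  make_signed(paste0("g", seq_len(N)), s, id)
}

sign_flip <- function(sig, id = paste0(attr(sig, "study_id"), "_flip")) {
  make_signed(sig$gene, -sig$sign1, id)
}

write_de_tsv <- function(path, gene, p, lfc,
                         header = "Gene.symbol\tP.Value\tlogFC") {
  writeLines(c(header, paste(gene, p, lfc, sep = "\t")), path)
  path
}

# Disease/treatment signature pair over a shared universe of `n_universe`
# genes in which the treatment's top-n down list contains exactly B of the
# disease's top-n up genes and its top-n up list exactly C of the disease's
# top-n down genes (A = D = 0). Used to realize printed per-quadrant counts.
make_reversal_pair <- function(B, C, n = 1000L, n_universe = 15000L) {
  stopifnot(B <= n, C <= n, n_universe >= 2L * n + 2L * n)
  up1 <- sprintf("U%04d", seq_len(n))
  dn1 <- sprintf("D%04d", seq_len(n))
  filler <- sprintf("F%05d", seq_len(n_universe - 2L * n))
  disease <- make_signed(c(up1, dn1, filler),
                         c(seq(n, 1), -seq(1, n), rep(0, length(filler))),
                         "disease")
  tr_up <- c(dn1[seq_len(C)], filler[seq_len(n - C)])
  tr_dn <- c(up1[seq_len(B)], filler[n - C + seq_len(n - B)])
  rest <- setdiff(disease$gene, c(tr_up, tr_dn))
  treatment <- make_signed(c(tr_up, tr_dn, rest),
                           c(seq(n, 1), -seq(1, n), rep(0, length(rest))),
                           "treatment")
  list(disease = disease, treatment = treatment)
}
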