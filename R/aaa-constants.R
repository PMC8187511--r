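## Kyte-Doolittle hydropathy scale; unknown residues (X, gaps) score 0
.kd_scale <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

.amino_acids <- names(.kd_scale)

## fixed reverse-translation table: one codon per residue
.codon_table <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
  E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTG", K = "AAA",
  M = "ATG", F = "TTT", P = "CCT", S = "TCT", T = "ACT", W = "TGG",
  Y = "TAT", V = "GTT"
)

## residue pools used by the sequence simulator; the transmembrane pool is
## restricted to strongly hydrophobic residues so a 21-mer run is always
## detected by the hydropathy screen, and the loop pool to strongly
## hydrophilic residues so adjacent runs never merge
.tm_pool   <- c("I", "L", "V", "F")
.loop_pool <- c("N", "Q", "E", "D", "K", "R", "H")

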