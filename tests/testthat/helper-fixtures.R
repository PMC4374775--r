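# Shared fixture builders. Everything is generated in code at test time.

table1_mg <- c(vmax = 183, ka = 0.38, kb = 0.16)

# a reference whose native contacts form a perfect matching: n well-separated
# two-atom clusters, pair partners 5 A apart (inside the 8 A cutoff), cluster
# spacing far beyond it, residue numbering spaced so every pair passes the
# sequence-separation filter
paired_reference <- function(n_pairs = 10, pair_distance = 5) {
  grp <- unlist(lapply(seq_len(n_pairs) - 1, function(k) list(
    ca_chain(1, start = c(k * 50, 0, 0)),
    ca_chain(1, start = c(k * 50 + pair_distance, 0, 0))
  )), recursive = FALSE)
  make_fixture_structure(grp)
}

random_rotation <- function(seed) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3)
  qr.Q(qr(m)) * sign(det(qr.Q(qr(m))))
}

transform_structure <- function(s, rot, shift) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(rot)
  s$atoms$x <- xyz[, 1] + shift[1]
  s$atoms$y <- xyz[, 2] + shift[2]
  s$atoms$z <- xyz[, 3] + shift[3]
  s
}

# apparent Michaelis parameters of the random-RE law at a fixed co-substrate
# level b: v = [Vmax b/(Kb+b)] * a/(Ka + a)
apparent_mm <- function(p, b) {
  c(v = unname(p["vmax"] * b / (p["kb"] + b)), km = unname(p["ka"]))
}
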