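# Shared fixtures: random sequences, brute-force oracles, toy profiles.

aa20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

random_protein_string <- function(n, seed) {
  set.seed(seed)
  paste(sample(aa20, n, replace = TRUE), collapse = "")
}

# independent pI oracle: fine grid scan for the sign change of the net
# charge (no bisection involved)
pi_gridscan <- function(seq, table = default_pka_table(), step = 1e-4) {
  ph <- seq(0, 14, by = step)
  Q <- protein_net_charge(seq, ph, table)
  i <- max(which(Q > 0))
  # linear interpolation inside the bracketing step
  ph[i] + (0 - Q[i]) * step / (Q[i + 1] - Q[i])
}

# hand-made mixture profile with an exactly linear charge curve
linear_mixture_profile <- function(k, pI = 7, ph = seq(0, 14, by = 0.01)) {
  C <- -k * (ph - pI)
  structure(list(ph = ph, C = C, q = C, q2 = C^2, mixture_pI = pI,
                 mean_n_units = 1, normalization = "weighted",
                 scale_factor = 1,
                 components = data.frame(id = "linear", weight = 1,
                                         kind = "protein")),
            class = "mixture_profile")
}

# pi_distribution stub from raw pI values (for criterion-only tests)
pi_distribution_from_values <- function(vals) {
  breaks <- seq(2, 13, by = 0.25)
  counts <- graphics::hist(pmin(pmax(vals, 2), 13), breaks = breaks,
                           plot = FALSE)$counts
  structure(list(pi_values = vals, breaks = breaks, counts = counts,
                 n = length(vals), skipped = 0L,
                 window_fractions = c(
                   near_neutral_7_8 = mean(vals > 7 & vals < 8),
                   above_7 = mean(vals > 7),
                   acidic_shoulder_4.5_6.5 = mean(vals > 4.5 & vals < 6.5),
                   basic_shoulder_8.5_10.5 = mean(vals > 8.5 & vals < 10.5))),
            class = "pi_distribution")
}

# class compositions whose pI windows are tightly pinned by many
# titrating groups near the target
acid_class_composition <- function() c(G = 0.7, H = 0.2, D = 0.1)   # ~5.9
base_class_composition <- function() c(G = 0.7, K = 0.2, C = 0.1)   # ~9.4
neutralish_class_composition <- function() c(G = 0.8, H = 0.2)      # 7-8

insulin_fixture <- function() {
  read_fasta_protein(system.file("extdata", "insulin.fasta",
                                 package = "condensateph"))
}
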