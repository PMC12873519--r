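# Shared fixtures, all built in code.

# Three-tip hand tree: ((A:1,B:1):1,C:2); depth 2, A-B share depth 1.
hand_tree3 <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# Star-like tree with one k-way polytomy at the root, unit tip edges.
polytomy_tree <- function(k = 4) {
  ape::read.tree(text = paste0(
    "(", paste(sprintf("t%d:1", seq_len(k)), collapse = ","), ");"))
}

# Tiny complete trait table with exact power-law structure (no noise).
exact_trait_table <- function(n = 10) {
  h <- 10^seq(log10(0.5), log10(40), length.out = n)
  l <- 10^(0.839 + 0.482 * log10(h))
  dpet <- 10^(0.898 + 0.396 * log10(l))
  dtwig <- 10^(0.592 + 0.679 * log10(dpet))
  wd <- 10^(-0.284 - 0.271 * log10(l))
  data.frame(species = sprintf("sp%03d", seq_len(n)),
             leaf_length_cm = l, d_pet_um = dpet, d_twig_um = dtwig,
             wood_density_g_cm3 = wd, height_m = h,
             leaf_type = rep(c("simple", "compound"), length.out = n),
             site = rep(c("site_1", "site_2"), length.out = n),
             stringsAsFactors = FALSE)
}

# A loglog_fit stub carrying just what compare_slopes() consumes; used to
# drive the Welch construction from externally reconstructed slope SEs.
slope_fit_stub <- function(slope, se, df, label = "y ~ x") {
  structure(list(slope = slope, slope_se = se, df_resid = df,
                 response = label, predictor = ""),
            class = "loglog_fit")
}
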