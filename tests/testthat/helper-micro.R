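# Shared micro-trained branch models, built once per test session and
# reused by the learning, wiring and inference tests.  The micro
# conditions: one 64x96x96 phantom at 1.5 mm with one anchor, two
# mid-level and one S&H structure; the anchor branch gets the full
# 200-iteration micro-overfit budget, the other branches shorter
# budgets sized to their role in the tests (guidance conditioning,
# peak regression, VOI segmentation).

micro_cache <- new.env(parent = emptyenv())

micro_phantom <- function() {
  if (!exists("phantom", micro_cache)) {
    micro_cache$phantom <- generate_phantom(
      phantom_config(n_anchor = 1, n_midlevel = 2, n_small_hard = 1,
                     seed = 7))
  }
  micro_cache$phantom
}

micro_models <- function() {
  if (!exists("models", micro_cache)) {
    ph <- micro_phantom()
    ts <- training_set(list(ph))
    gen <- genotype(rep("3D3", n_search_blocks(2L)), levels = 2, base = 8)
    pres <- function(stratum)
      intersect(oar_names(stratum = stratum), names(ph$labels$masks))
    micro_cache$models <- list(
      anchor_seg = train_branch(
        ts, "anchor_seg", gen,
        train_config(iterations = 200, classes = pres("anchor")),
        seed = 1),
      mid_seg = train_branch(
        ts, "mid_seg", gen,
        train_config(iterations = 40, classes = pres("mid-level")),
        seed = 2),
      sh_detect = train_branch(
        ts, "sh_detect", gen,
        train_config(iterations = 250, classes = pres("small_hard")),
        seed = 3),
      sh_seg = train_branch(
        ts, "sh_seg", gen,
        train_config(iterations = 80, patch = c(16L, 16L, 16L),
                     classes = pres("small_hard")),
        seed = 4))
  }
  micro_cache$models
}

micro_anchor_pred <- function() {
  if (!exists("anchor_pred", micro_cache)) {
    micro_cache$anchor_pred <-
      predict_anchor(micro_phantom()$image, micro_models()$anchor_seg)
  }
  micro_cache$anchor_pred
}

# a genotype/backbone small enough for fast structural tests
tiny_genotype <- function(codes = rep("3D3", 6))
  genotype(codes, levels = 2, base = 2)
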