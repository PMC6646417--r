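# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Deterministic sub-seed per simulation stage so changing one knob perturbs
# only its own random stream. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483629L)
}

with_stage_seed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stage_seed(seed, stage))
  force(expr)
}

assert_scalar_string <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(sprintf("`%s` must be a non-empty string", name), call. = FALSE)
  }
  invisible(x)
}

VALID_EFFECTS <- c("missense", "insertion", "deletion", "frameshift", "stop_gained")

# Standard genetic code as a codon -> single-letter lookup ("*" = stop).
CODON_TABLE <- Biostrings::GENETIC_CODE

AA_STANDARD <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

CGVHD_GRADES <- c("no", "limited", "extensive")

GVHD_TARGET_TISSUES <- c("skin", "intestine", "lung", "liver", "bone marrow")

HLA_LOCI <- c("A", "B", "C", "DRB1", "DQB1", "DPB1")
HLA_CLASS1_LOCI <- c("A", "B", "C")
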