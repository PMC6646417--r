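# Independent brute-force oracles and fixture builders. These deliberately
# share no code path with the package: haplotypes are rebuilt character by
# character, translation loops over codons, peptide sets are enumerated by
# nested loops, and the logistic reference fitter is a hand-written IRLS.

make_reference <- function(ids, cds, genes = paste0("G_", ids)) {
  structure(
    tibble::tibble(transcript_id = ids, gene_id = genes, cds = cds),
    class = c("cds_reference", class(tibble::tibble()))
  )
}

make_variants <- function(...) {
  tbl <- tibble::tibble(...)
  defaults <- list(dp = 99, gq = 99, missing = FALSE)
  for (nm in names(defaults)) if (!nm %in% names(tbl)) tbl[[nm]] <- defaults[[nm]]
  structure(tbl, class = c("variant_calls", class(tibble::tibble())))
}

make_proteome <- function(sample_id, proteins, genes = NULL) {
  if (is.null(genes)) genes <- stats::setNames(paste0("G_", names(proteins)), names(proteins))
  structure(list(sample_id = sample_id, proteins = proteins, genes = genes),
            class = "individual_proteome")
}

make_typing <- function(sample_id, alleles) {
  structure(list(sample_id = sample_id, alleles = alleles), class = "hla_typing")
}

full_typing <- function(sample_id, A = c("A*01:01", "A*02:01"),
                        B = c("B*07:02", "B*08:01"),
                        C = c("C*07:01", "C*07:02"),
                        DRB1 = c("DRB1*01:01", "DRB1*03:01"),
                        DQB1 = c("DQB1*02:01", "DQB1*03:01"),
                        DPB1 = c("DPB1*04:01", "DPB1*02:01")) {
  make_typing(sample_id, list(A = A, B = B, C = C, DRB1 = DRB1, DQB1 = DQB1, DPB1 = DPB1))
}

make_ligand_db <- function(kind, ligands) {
  structure(list(kind = kind, ligands = ligands), class = "ligand_db")
}

# --- sequence-level oracles ------------------------------------------------

# ascending-order, offset-tracking rebuild (different algorithm from the
# descending in-place edits of the implementation)
oracle_apply <- function(cds, variants) {
  if (nrow(variants) == 0L) return(cds)
  v <- variants[order(variants$cds_pos), , drop = FALSE]
  chars <- strsplit(cds, "")[[1]]
  out <- character(0)
  i <- 1L
  vi <- 1L
  while (i <= length(chars)) {
    if (vi <= nrow(v) && i == v$cds_pos[vi]) {
      stopifnot(paste(chars[i:(i + nchar(v$ref[vi]) - 1L)], collapse = "") == v$ref[vi])
      out <- c(out, strsplit(v$alt[vi], "")[[1]])
      i <- i + nchar(v$ref[vi])
      vi <- vi + 1L
    } else {
      out <- c(out, chars[i])
      i <- i + 1L
    }
  }
  paste(out, collapse = "")
}

oracle_translate <- function(cds) {
  code <- Biostrings::GENETIC_CODE
  aa <- character(0)
  i <- 1L
  while (i + 2L <= nchar(cds)) {
    codon <- substr(cds, i, i + 2L)
    r <- if (codon %in% names(code)) code[[codon]] else "X"
    if (r == "*") return(paste(aa, collapse = ""))
    aa <- c(aa, r)
    i <- i + 3L
  }
  paste(aa, collapse = "")
}

oracle_kmers <- function(protein, k = 9L) {
  out <- character(0)
  if (nchar(protein) >= k) {
    for (i in 1:(nchar(protein) - k + 1L)) {
      w <- substr(protein, i, i + k - 1L)
      if (!grepl("X", w, fixed = TRUE)) out <- c(out, w)
    }
  }
  unique(out)
}

# per-subject proteome as a plain list transcript -> protein set
oracle_proteome <- function(sample_id, reference, variants) {
  out <- list()
  for (i in seq_len(nrow(reference))) {
    tx <- reference$transcript_id[i]
    v <- variants[variants$sample_id == sample_id & variants$transcript_id == tx &
                    !variants$missing & variants$dosage > 0L, , drop = FALSE]
    if (nrow(v) == 0L) {
      out[[tx]] <- oracle_translate(reference$cds[i])
    } else {
      h2 <- oracle_translate(oracle_apply(reference$cds[i], v))
      h1 <- oracle_translate(oracle_apply(reference$cds[i], v[v$dosage == 2L, , drop = FALSE]))
      prods <- unique(c(h1, h2))
      out[[tx]] <- prods[nzchar(prods)]
    }
  }
  out
}

oracle_recipient_unique <- function(donor_prot, recipient_prot, k = 9L) {
  diff_tx <- names(donor_prot)[vapply(names(donor_prot), function(t) {
    !setequal(donor_prot[[t]], recipient_prot[[t]])
  }, logical(1))]
  rec <- unique(unlist(lapply(diff_tx, function(t) {
    unlist(lapply(recipient_prot[[t]], oracle_kmers, k = k))
  })))
  don <- unique(unlist(lapply(diff_tx, function(t) {
    unlist(lapply(donor_prot[[t]], oracle_kmers, k = k))
  })))
  as.character(setdiff(rec, don))
}

oracle_imm_score <- function(peptide, weights_tbl, pos_weights) {
  s <- 0
  for (i in seq_len(nchar(peptide))) {
    aa <- substr(peptide, i, i)
    s <- s + pos_weights[i] * weights_tbl$log_enrichment[weights_tbl$residue == aa]
  }
  s
}

# --- logistic IRLS reference fitter ---------------------------------------

irls_logistic <- function(X, y, max_iter = 200L, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- solve(XtW %*% X, XtW %*% z)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  w <- mu * (1 - mu)
  se <- sqrt(diag(solve(t(X * w) %*% X)))
  list(estimate = drop(beta), std_error = se)
}

# --- random micro-instance generator for oracle-equivalence checks --------

BASES <- c("A", "C", "G", "T")

random_micro_cds <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- all_cods <- apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")
  body <- sample(setdiff(all_cods, stops), n_codons - 2L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), sample(stops, 1L))
}

random_micro_instance <- function() {
  n_tx <- sample(1:5, 1L)
  ref <- make_reference(
    ids = paste0("T", seq_len(n_tx)),
    cds = vapply(sample(15:30, n_tx, replace = TRUE), random_micro_cds, character(1))
  )
  rows <- list()
  n_var <- sample(0:4, 1L)
  if (n_var > 0L) {
    for (v in seq_len(n_var)) {
      i <- sample(n_tx, 1L)
      cds <- ref$cds[i]
      n_codons <- nchar(cds) %/% 3L
      codon <- sample(seq(3L, n_codons - 2L, by = 4L), 1L)
      p <- 3L * (codon - 1L) + 1L
      kind <- sample(c("sub", "ins", "del"), 1L)
      if (kind == "sub") {
        ref_a <- substr(cds, p, p)
        ed <- list(pos = p, ref = ref_a, alt = sample(setdiff(BASES, ref_a), 1L))
      } else if (kind == "ins") {
        ref_a <- substr(cds, p, p)
        ed <- list(pos = p, ref = ref_a,
                   alt = paste0(ref_a, paste(sample(BASES, sample(1:3, 1L), replace = TRUE),
                                             collapse = "")))
      } else {
        len <- sample(1:3, 1L)
        ed <- list(pos = p, ref = substr(cds, p, p + len), alt = substr(cds, p, p))
      }
      dosages <- sample(0:2, 2L, replace = TRUE)
      if (all(dosages == 0L)) dosages[sample(1:2, 1L)] <- 1L
      rows[[v]] <- tibble::tibble(
        transcript_id = ref$transcript_id[i], cds_pos = ed$pos,
        ref = ed$ref, alt = ed$alt, effect = "missense",
        sample_id = c("D", "R"), dosage = rep(dosages, each = 1L),
        dp = 99, gq = 99, missing = FALSE
      )
    }
  }
  vars <- if (length(rows)) dplyr::bind_rows(rows) else
    make_variants(transcript_id = character(0), cds_pos = integer(0),
                  ref = character(0), alt = character(0), effect = character(0),
                  sample_id = character(0), dosage = integer(0))
  # drop colliding duplicate positions on the same transcript
  vars <- vars[!duplicated(paste(vars$transcript_id, vars$cds_pos, vars$sample_id)), ]
  keys <- unique(vars[, c("transcript_id", "cds_pos")])
  keep <- rep(TRUE, nrow(keys))
  if (nrow(keys) > 1L) {
    for (a in 1:(nrow(keys) - 1L)) for (b in (a + 1L):nrow(keys)) {
      if (keys$transcript_id[a] == keys$transcript_id[b] &&
          abs(keys$cds_pos[a] - keys$cds_pos[b]) < 8L) keep[b] <- FALSE
    }
  }
  vars <- dplyr::semi_join(vars, keys[keep, ], by = c("transcript_id", "cds_pos"))
  list(reference = ref,
       variants = structure(vars, class = c("variant_calls", class(tibble::tibble()))))
}
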