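#' Posterior effect-size draws for one gene
#'
#' Converts the interaction posterior into a per-gene scalar effect. The
#' default effect is the prior-centered outgoing interaction row sum: per
#' draw `s`,
#' \deqn{\delta_g(s) = \sum_{j \ne g} \phi_{gj}(s) - (N - 1)\, a_0 / b_0,}
#' the total strength with which gene `g` tilts the other genes, centered
#' at its prior expectation so that a gene whose interactions never moved
#' from the prior scores zero. Interaction draws are taken from the gamma
#' variational posterior. Two variants are available: the uncentered row
#' sum (`effect = "rowsum"`), and a latent-state magnitude
#' (`effect = "state"`: per draw the root-mean-square of the gene's latent
#' trajectory, requiring `stateSamples`).
#'
#' @param fit a [VbFit].
#' @param gene gene label or index.
#' @param nDraws number of posterior draws (default 2000).
#' @param seed integer seed for the gamma draws.
#' @param effect effect definition; see Details.
#' @param stateSamples a [PosteriorSamples] (only for `effect = "state"`).
#' @return list with `gene`, `draws` (length `nDraws`), `mu` (posterior
#'   mean of the effect), `sigma` (posterior sd).
#' @export
geneEffectSamples <- function(fit, gene, nDraws = 2000L, seed = 1L,
                              effect = c("centered_rowsum", "rowsum",
                                "state"),
                              stateSamples = NULL) {
  effect <- match.arg(effect)
  stopIfNot(is(fit, "VbFit"), "fit must be a VbFit")
  gp <- fit@interactionPosterior
  N <- nrow(gp@shape)
  genes <- rownames(gp@shape)
  if (is.character(gene)) {
    stopIfNot(gene %in% genes, "invalid-argument: unknown gene")
    g <- match(gene, genes)
  } else {
    stopIfNot(gene >= 1 && gene <= N, "invalid-argument: unknown gene")
    g <- as.integer(gene)
  }
  label <- if (!is.null(genes)) genes[g] else paste0("gene", g)
  if (effect == "state") {
    stopIfNot(is(stateSamples, "PosteriorSamples"),
      "effect = 'state' requires stateSamples")
    K <- stateSamples@K
    idx <- stackIndex(g, seq_len(K), K)
    draws <- sqrt(rowMeans(stateSamples@draws[, idx, drop = FALSE]^2))
  } else {
    others <- setdiff(seq_len(N), g)
    draws <- withSeed(seed, {
      if (length(others) == 0) {
        rep(0, nDraws)
      } else {
        phi <- matrix(
          rgamma(nDraws * length(others),
            shape = rep(gp@shape[g, others], each = nDraws),
            rate = rep(gp@rate[g, others], each = nDraws)
          ),
          nrow = nDraws
        )
        rowSums(phi)
      }
    })
    if (effect == "centered_rowsum") {
      a0 <- fit@settings$a0
      b0 <- fit@settings$b0
      draws <- draws - (N - 1) * a0 / b0
    }
  }
  list(
    gene = label, draws = draws,
    mu = mean(draws), sigma = stats::sd(draws)
  )
}

#' Driver coefficient
#'
#' The squared posterior signal-to-noise ratio `(mu / sigma)^2` of a gene's
#' effect size: large when the effect is both strong and precisely
#' estimated. A degenerate posterior (`sigma = 0`) with a non-zero mean is
#' an error; with a zero mean the coefficient is defined as 0 by convention
#' (reported via a message).
#'
#' @param mu posterior mean effect.
#' @param sigma posterior sd of the effect (>= 0).
#' @return non-negative driver coefficient.
#' @examples
#' drCoef(0, 1) # 0: no effect
#' drCoef(3, 0.5) # 36: strong, precise effect
#' @export
drCoef <- function(mu, sigma) {
  stopIfNot(sigma >= 0, "sigma must be non-negative")
  if (sigma == 0) {
    if (mu != 0) {
      stop("degenerate-posterior: sigma = 0 with non-zero mean",
        call. = FALSE)
    }
    message("drCoef: mu = sigma = 0, returning 0 by convention")
    return(0)
  }
  (mu / sigma)^2
}

#' Rank genes by driver coefficient
#'
#' Computes the driver coefficient for each gene from its effect-sample
#' moments, attaches the highest-density interval of the effect draws, and
#' returns the table sorted by coefficient (descending), with a
#' deterministic lexicographic tie-break so permuting the input order never
#' changes the result.
#'
#' @param effectSamples list of per-gene effect samples as produced by
#'   [geneEffectSamples].
#' @param hdiMass HDI mass (default 0.95).
#' @param knownGenes optional character vector of known driver symbols used
#'   to flag rows (case-insensitive match).
#' @return data.frame with columns `gene`, `drCoef`, `hdiLower`,
#'   `hdiUpper`, `rank`, and `known` when `knownGenes` is given.
#' @export
rankDrivers <- function(effectSamples, hdiMass = 0.95, knownGenes = NULL) {
  stopIfNot(length(effectSamples) >= 1, "at least one gene is required")
  rows <- lapply(effectSamples, function(e) {
    iv <- hdi(e$draws, hdiMass)
    data.frame(
      gene = e$gene, drCoef = drCoef(e$mu, e$sigma),
      hdiLower = unname(iv["lower"]), hdiUpper = unname(iv["upper"])
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$drCoef, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  if (!is.null(knownGenes)) {
    out$known <- toupper(out$gene) %in% toupper(knownGenes)
  }
  rownames(out) <- NULL
  out
}

#' Driver coefficients across cell types
#'
#' Assembles per-cell-type driver tables (each from an independent run of
#' the pipeline on that cell type's trajectories) into a genes x cell-types
#' matrix restricted to a gene subset. Genes absent from a cell type's
#' table are `NA` (masked), never zero-filled.
#'
#' @param perTypeTables named list of driver tables from [rankDrivers].
#' @param geneSubset character vector of genes to keep (e.g., the top 30
#'   from the progenitor cell type).
#' @return numeric matrix, `length(geneSubset)` x `length(perTypeTables)`.
#' @export
crossTypeScores <- function(perTypeTables, geneSubset) {
  stopIfNot(length(perTypeTables) >= 1,
    "at least one cell-type table is required")
  stopIfNot(!is.null(names(perTypeTables)),
    "perTypeTables must be a named list")
  out <- matrix(NA_real_, length(geneSubset), length(perTypeTables),
    dimnames = list(geneSubset, names(perTypeTables))
  )
  any_hit <- FALSE
  for (nm in names(perTypeTables)) {
    tab <- perTypeTables[[nm]]
    idx <- match(geneSubset, tab$gene)
    hit <- !is.na(idx)
    if (any(hit)) any_hit <- TRUE
    out[hit, nm] <- tab$drCoef[idx[hit]]
  }
  if (!any_hit) {
    warning("empty-result: no gene of the subset appears in any table")
  }
  out
}

#' Overlap of top-ranked genes with a known driver list
#'
#' Percentage of the top `topK` ranked genes present in a known driver
#' list, matched case-insensitively on the gene symbol.
#'
#' @param driverTable a table from [rankDrivers].
#' @param knownGenes character vector of known driver symbols.
#' @param topK number of top-ranked genes to consider
#'   (<= `nrow(driverTable)`).
#' @return percentage in `[0, 100]`.
#' @export
overlapWithKnown <- function(driverTable, knownGenes, topK = 30L) {
  stopIfNot(topK >= 1 && topK <= nrow(driverTable),
    "topK must be between 1 and the table size")
  if (length(knownGenes) == 0) {
    warning("known driver list is empty; overlap is 0%")
    return(0)
  }
  top <- driverTable$gene[order(driverTable$rank)][seq_len(topK)]
  100 * mean(toupper(top) %in% toupper(knownGenes))
}
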