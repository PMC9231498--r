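#' Evolve a provirus copy forward in time
#'
#' Simulates the post-integration evolution of a single proviral copy. The
#' 5' LTR, internal region and 3' LTR mutate independently: each site is
#' substituted with probability `mu * age_years` (single-hit regime of a
#' Jukes-Cantor clock, uniform choice among the three alternative bases), and
#' short indels (length 1-3) are placed at rate `indel_rate * age_years` per
#' site. Because the two LTRs are identical at integration and then diverge
#' independently, the expected observed LTR-pair divergence is `2 * mu * age`.
#'
#' @param template A [provirus_template()].
#' @param age_years Time since integration (years, >= 0).
#' @param mu Substitution rate (substitutions / site / year, > 0).
#' @param indel_rate Indel rate (indels / site / year, >= 0).
#' @param seed Integer seed.
#' @return An object of class `erv_copy`: list with `ltr5`, `internal`,
#'   `ltr3`, `seq` (their concatenation), `log` (data frame of mutation
#'   events: region, pos (0-based, template coordinates), type sub/ins/del,
#'   len, ref, alt, gene), and `pol_truth` (list `n_stops`, `n_frameshifts`
#'   as implied by the mutation process, for cross-checking annotation).
#' @examples
#' tpl <- provirus_template(seed = 1)
#' cp <- evolve_copy(tpl, age_years = 0, mu = 2e-9, seed = 1)
#' identical(cp$ltr5, cp$ltr3)
#' @export
evolve_copy <- function(template, age_years, mu, indel_rate = 0, seed = 1L) {
  if (age_years < 0) stop("age_years must be >= 0", call. = FALSE)
  if (mu < 0 || indel_rate < 0) stop("rates must be >= 0", call. = FALSE)
  p_sub <- min(mu * age_years, 0.75)
  lambda <- indel_rate * age_years

  with_seed(seed, {
    regions <- list(ltr5 = template$ltr, internal = template$internal,
                    ltr3 = template$ltr)
    logs <- list()
    out <- list()
    for (rn in names(regions)) {
      ev <- evolve_region(regions[[rn]], p_sub, lambda)
      if (nrow(ev$log)) ev$log$region <- rn
      logs[[rn]] <- ev$log
      out[[rn]] <- ev$seq
      if (rn == "internal") internal_sub_only <- ev$sub_only
    }
    log <- do.call(rbind, logs[vapply(logs, nrow, 1L) > 0])
    if (is.null(log)) {
      log <- data.frame(region = character(), pos = integer(),
                        type = character(), len = integer(),
                        ref = character(), alt = character(),
                        stringsAsFactors = FALSE)
    }
    rownames(log) <- NULL
    log$gene <- gene_at(log$pos, log$region, template$gene_map)

    pol <- template$gene_map$pol
    pol_sub <- substr(internal_sub_only, pol[1] + 1L, pol[2])
    pol_log <- log[log$region == "internal" & !is.na(log$gene) &
                     log$gene == "pol", , drop = FALSE]
    pol_truth <- list(
      n_stops = count_stop_codons(pol_sub),
      n_frameshifts = sum(pol_log$type != "sub" & pol_log$len %% 3L != 0L))

    structure(list(ltr5 = out$ltr5, internal = out$internal, ltr3 = out$ltr3,
                   seq = paste0(out$ltr5, out$internal, out$ltr3),
                   log = log, pol_truth = pol_truth,
                   age_years = age_years),
              class = "erv_copy")
  })
}

## Substitutions then indels on one region. Indel positions are drawn in
## template coordinates and applied right-to-left so logged coordinates stay
## in the template frame. Returns the final sequence, the substitutions-only
## sequence (for stop-codon truth) and the event log.
evolve_region <- function(seq, p_sub, lambda) {
  ch <- seq_chars(seq)
  n <- length(ch)
  log <- list()
  hit <- which(runif(n) < p_sub)
  if (length(hit)) {
    ref <- ch[hit]
    alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L),
                  character(1))
    ch[hit] <- alt
    log$sub <- data.frame(pos = hit - 1L, type = "sub", len = 1L,
                          ref = ref, alt = alt, stringsAsFactors = FALSE)
  }
  sub_only <- paste(ch, collapse = "")

  n_indel <- rpois(1L, lambda * n)
  if (n_indel > 0L) {
    pos <- sort(sample.int(n, n_indel, replace = FALSE), decreasing = TRUE)
    len <- sample(1:3, n_indel, replace = TRUE)
    ins <- runif(n_indel) < 0.5
    rows <- vector("list", n_indel)
    for (i in seq_len(n_indel)) {
      p <- pos[i]; l <- len[i]
      if (ins[i]) {
        piece <- sample(DNA_BASES, l, replace = TRUE)
        ch <- append(ch, piece, after = p)
        rows[[i]] <- data.frame(pos = p - 1L, type = "ins", len = l,
                                ref = "", alt = paste(piece, collapse = ""),
                                stringsAsFactors = FALSE)
      } else {
        l <- min(l, length(ch) - p + 1L)
        rows[[i]] <- data.frame(pos = p - 1L, type = "del", len = l,
                                ref = paste(ch[p:(p + l - 1L)], collapse = ""),
                                alt = "", stringsAsFactors = FALSE)
        ch <- ch[-(p:(p + l - 1L))]
      }
    }
    log$indel <- do.call(rbind, rows)
  }
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(pos = integer(), type = character(), len = integer(),
               ref = character(), alt = character(), stringsAsFactors = FALSE)
  list(seq = paste(ch, collapse = ""), sub_only = sub_only, log = log)
}

gene_at <- function(pos, region, gene_map) {
  out <- rep(NA_character_, length(pos))
  for (g in names(gene_map)) {
    iv <- gene_map[[g]]
    sel <- region == "internal" & pos >= iv[1] & pos < iv[2]
    out[sel] <- g
  }
  out
}

count_stop_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(0L)
  starts <- (seq_len(n) - 1L) * 3L + 1L
  codons <- substring(seq, starts, starts + 2L)
  sum(codons %in% c("TAA", "TAG", "TGA"))
}
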