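#' Construct an ancestral provirus template
#'
#' Builds a canonical provirus: two identical long terminal repeats (LTRs)
#' flanking an internal region carrying gag, pro, pol and env genes in order.
#' Each gene is generated as a single open reading frame (an ATG followed by
#' non-stop codons) so that premature stops and frameshifts in descendant
#' copies are unambiguously mutation-derived. Untranslated leader/trailer
#' spacers separate the genes from the LTRs.
#'
#' @param ltr_len LTR length in bases (default 500).
#' @param gene_lens Named numeric vector of gene lengths (bases, multiples of
#'   3) for `gag`, `pro`, `pol`, `env`.
#' @param utr_len Length of untranslated spacer placed before gag and after
#'   env inside the internal region.
#' @param seed Integer seed; the template is a deterministic function of it.
#' @return An object of class `provirus_template`: a list with `ltr`
#'   (character), `internal` (character), `gene_map` (named list of 0-based
#'   half-open `c(start, end)` intervals within `internal`), and `ltr_len`.
#' @examples
#' tpl <- provirus_template(seed = 1)
#' nchar(template_sequence(tpl)) == 2 * tpl$ltr_len + nchar(tpl$internal)
#' @export
provirus_template <- function(ltr_len = 500L,
                              gene_lens = c(gag = 1500L, pro = 900L,
                                            pol = 2700L, env = 1800L),
                              utr_len = 200L,
                              seed = 1L) {
  stopifnot(ltr_len >= 50L, all(gene_lens %% 3L == 0L),
            identical(names(gene_lens), c("gag", "pro", "pol", "env")))
  with_seed(seed, {
    ltr <- random_dna(ltr_len)
    genes <- lapply(gene_lens, random_orf)
    gene_map <- list()
    offset <- utr_len
    pieces <- list(random_dna(utr_len))
    for (g in names(genes)) {
      gene_map[[g]] <- c(offset, offset + nchar(genes[[g]]))
      pieces <- c(pieces, genes[[g]])
      offset <- offset + nchar(genes[[g]])
    }
    pieces <- c(pieces, random_dna(utr_len))
    structure(list(ltr = ltr,
                   internal = paste(unlist(pieces), collapse = ""),
                   gene_map = gene_map,
                   ltr_len = as.integer(ltr_len)),
              class = "provirus_template")
  })
}

## An ORF of n bases: ATG then codons drawn from the 60 non-stop, non-ATG-free
## codon set (stops excluded so the template frame is open throughout).
random_orf <- function(n) {
  stopifnot(n %% 3L == 0L, n >= 6L)
  codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1L,
                  paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste0("ATG", paste(sample(codons, n / 3L - 1L, replace = TRUE),
                      collapse = ""))
}

#' Full nucleotide sequence of a provirus template
#' @param template A `provirus_template`.
#' @return Character scalar: 5'LTR + internal + 3'LTR.
#' @export
template_sequence <- function(template) {
  paste0(template$ltr, template$internal, template$ltr)
}

#' Derive per-lineage provirus templates from a shared ancestor
#'
#' Each lineage template is the ancestral template evolved by a fixed
#' divergence, so lineages are recognisably related but distinguishable: a
#' soft-clip matching its own lineage LTR at ~100% identity matches the other
#' lineages appreciably worse, making best-match lineage assignment stable.
#'
#' @param template Ancestral `provirus_template`.
#' @param lineage_names Character vector of lineage labels.
#' @param divergence Per-lineage divergence from the ancestor
#'   (substitutions/site; default 0.10).
#' @param seed Integer seed.
#' @return Named list of `provirus_template` objects.
#' @export
lineage_templates <- function(template, lineage_names,
                              divergence = 0.10, seed = 1L) {
  out <- lapply(seq_along(lineage_names), function(i) {
    s <- derive_seed(seed, 100L + i)
    with_seed(s, {
      tpl <- template
      tpl$ltr <- mutate_string(template$ltr, divergence)
      tpl$internal <- mutate_string(template$internal, divergence)
      tpl
    })
  })
  setNames(out, lineage_names)
}

## Substitute each site independently with probability p (uniform among the
## three alternative bases). Uses the current RNG stream.
mutate_string <- function(x, p) {
  ch <- seq_chars(x)
  hit <- which(runif(length(ch)) < p)
  if (length(hit)) {
    for (i in hit) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

#' Build the ERV mapping library from lineage templates
#'
#' @param templates Named list of `provirus_template` (per lineage).
#' @return List with `contigs` (named character: full-length consensus per
#'   lineage, names `lib_<lineage>`) and `ltrs` (named character: consensus
#'   LTR per lineage).
#' @export
erv_library <- function(templates) {
  list(contigs = setNames(vapply(templates, template_sequence, character(1)),
                          paste0("lib_", names(templates))),
       ltrs = setNames(vapply(templates, function(t) t$ltr, character(1)),
                       names(templates)))
}

is_library_contig <- function(x) startsWith(x, "lib_")

#' Write / read a template gene map JSON sidecar
#' @param template A `provirus_template`.
#' @param path JSON path.
#' @export
write_gene_map <- function(template, path) {
  jsonlite::write_json(
    list(ltr_len = template$ltr_len, gene_map = template$gene_map),
    path, auto_unbox = TRUE)
  invisible(path)
}
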