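# Haploid porcine sperm karyotype, centromeric probe classes and the
# Mendelian segregation model for a heterozygous Robertsonian t(13;17).

.ACROCENTRIC <- paste0("SSC", 13:18)
.UNLABELED   <- c("SSC1", "SSC12")

#' Build a haploid porcine sperm karyotype
#'
#' A normal boar sperm nucleus carries 18 autosomes plus one gonosome
#' (19 chromosomes, 38 telomeres). In a balanced gamete carrying the
#' Robertsonian translocation t(13;17) the acrocentric chromosomes SSC13 and
#' SSC17 are replaced by a single centromeric-fusion product, giving 18
#' chromosomes and 36 telomeres. Each chromosome carries a centromere class
#' matching the two porcine centromeric satellite probe families: `AC6`
#' labels acrocentric centromeres (SSC13-SSC18), `SSCRS2A` labels
#' (sub)metacentric centromeres (SSC2-SSC11 and the gonosome); SSC1 and
#' SSC12 are labelled by neither probe.
#'
#' The fusion product is modelled with a single acrocentric-class centromere:
#' the merged centromeric satellite blocks appear as one AC6 signal, so one
#' AC6-labelled centromere is lost relative to the control karyotype.
#' Gonosome identity is a property of the individual nucleus (each sperm
#' carries X or Y), so the karyotype holds a single gonosome entry.
#'
#' @param fused logical; `TRUE` builds the t(13;17) balanced-gamete karyotype.
#' @param gonosome `"X"` or `"Y"`, the sex chromosome carried by this gamete.
#' @return An object of class `karyotype`: a list with a `chromosomes`
#'   data frame (`name`, `centromere_class`, `telomere_count`), plus
#'   `is_fused_13_17` and `gonosome` flags.
#' @examples
#' k <- build_haploid_karyotype()
#' n_chromosomes(k)   # 19
#' n_telomeres(k)     # 38
#' kf <- build_haploid_karyotype(fused = TRUE)
#' n_telomeres(kf)    # 36
#' @export
build_haploid_karyotype <- function(fused = FALSE, gonosome = c("X", "Y")) {
  stopifnot(is.logical(fused), length(fused) == 1L, !is.na(fused))
  gonosome <- match.arg(gonosome)
  autosomes <- paste0("SSC", 1:18)
  if (fused) {
    autosomes <- autosomes[!autosomes %in% c("SSC13", "SSC17")]
    autosomes <- append(autosomes, "SSC13;17", after = 12L)
  }
  nm <- c(autosomes, paste0("SSC", gonosome))
  cls <- vapply(nm, function(x) {
    if (x %in% .UNLABELED) "unlabeled"
    else if (x %in% c(.ACROCENTRIC, "SSC13;17")) "acrocentric"
    else "submeta_or_metacentric"
  }, character(1), USE.NAMES = FALSE)
  k <- list(
    chromosomes = data.frame(name = nm, centromere_class = cls,
                             telomere_count = 2L, stringsAsFactors = FALSE),
    is_fused_13_17 = fused,
    gonosome = gonosome
  )
  class(k) <- "karyotype"
  k
}

#' @export
print.karyotype <- function(x, ...) {
  cat(sprintf("Haploid porcine sperm karyotype (%s)\n",
              if (x$is_fused_13_17) "t(13;17) balanced gamete" else "control"))
  cat(sprintf("  %d chromosomes, %d telomeres, gonosome SSC%s\n",
              n_chromosomes(x), n_telomeres(x), x$gonosome))
  cat(sprintf("  labelled centromeres: AC6 = %d, SSCRS2A = %d\n",
              labeled_centromere_count(x, "AC6"),
              labeled_centromere_count(x, "SSCRS2A")))
  invisible(x)
}

#' Number of chromosomes in a karyotype
#' @param k a `karyotype`.
#' @return integer count.
#' @export
n_chromosomes <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  nrow(k$chromosomes)
}

#' Total telomere count of a karyotype
#'
#' Every (possibly fused) chromosome contributes two telomeres, so the total
#' is twice the chromosome count: 38 for a control gamete, 36 for a balanced
#' t(13;17) gamete.
#' @param k a `karyotype`.
#' @return integer count.
#' @export
n_telomeres <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  sum(k$chromosomes$telomere_count)
}

#' Count centromeres labelled by a centromeric satellite probe
#'
#' `AC6` recognises the acrocentric centromeric satellite family (6 signals
#' in a control gamete; 5 in a fused gamete because the t(13;17) fusion
#' merges the SSC13 and SSC17 centromeric blocks into one). `SSCRS2A`
#' recognises the (sub)metacentric family (11 signals in either karyotype:
#' SSC2-SSC11 plus the gonosome; SSC1 and SSC12 are not labelled).
#'
#' @param k a `karyotype`.
#' @param probe `"AC6"` or `"SSCRS2A"`.
#' @return integer count of labelled centromeres.
#' @examples
#' labeled_centromere_count(build_haploid_karyotype(), "AC6")          # 6
#' labeled_centromere_count(build_haploid_karyotype(), "SSCRS2A")      # 11
#' labeled_centromere_count(build_haploid_karyotype(fused = TRUE), "AC6") # 5
#' @export
labeled_centromere_count <- function(k, probe) {
  stopifnot(inherits(k, "karyotype"))
  if (!is.character(probe) || length(probe) != 1L ||
      !probe %in% c("AC6", "SSCRS2A")) {
    stop("unknown probe: must be \"AC6\" or \"SSCRS2A\"")
  }
  target <- switch(probe, AC6 = "acrocentric", SSCRS2A = "submeta_or_metacentric")
  sum(k$chromosomes$centromere_class == target)
}

#' Segregation-model parameters for a heterozygous Robertsonian carrier
#'
#' @param carrier_gamete_fusion_fraction fraction of balanced gametes that
#'   carry the fused chromosome; 0.5 for a heterozygous carrier producing
#'   equal numbers of translocated and normal balanced sperm.
#' @param baseline_proximal_fraction fraction of control nuclei whose SSC13
#'   and SSC17 territories are colocalized or adjacent. Defaults to 0.5, the
#'   rounded control condition (observed 16% colocalized + 32% adjacent =
#'   0.48, available as an override).
#' @return a `segregation_params` list.
#' @export
segregation_params <- function(carrier_gamete_fusion_fraction = 0.5,
                               baseline_proximal_fraction = 0.5) {
  f <- carrier_gamete_fusion_fraction
  b <- baseline_proximal_fraction
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f < 0 || f > 1)
    stop("carrier_gamete_fusion_fraction must be a probability in [0, 1]")
  if (!is.numeric(b) || length(b) != 1L || is.na(b) || b < 0 || b > 1)
    stop("baseline_proximal_fraction must be a probability in [0, 1]")
  structure(list(carrier_gamete_fusion_fraction = f,
                 baseline_proximal_fraction = b),
            class = "segregation_params")
}

#' Expected territory-proximity proportions in carrier sperm
#'
#' Mendelian segregation model for the SSC13/SSC17 pair category in sperm of
#' a heterozygous t(13;17) carrier. A fraction `f` of balanced gametes
#' carries the fused chromosome, whose two painted territories are always
#' colocalized or adjacent ("proximal"); the remaining `1 - f` behave like
#' control nuclei, of which a fraction `b` is proximal. The expected
#' proximal fraction is therefore `f + (1 - f) * b` and the distant fraction
#' is its complement. With `f = 0.5` and `b = 0.5` (half the control nuclei
#' proximal) this yields the 75% / 25% expectation.
#'
#' @param params a [segregation_params()] object; alternatively pass the two
#'   probabilities directly via `...` positional shortcuts.
#' @return named numeric vector `c(proximal = , distant = )`, summing to 1.
#' @examples
#' expected_category_proportions(segregation_params(0.5, 0.5))  # 0.75 0.25
#' @export
expected_category_proportions <- function(params = segregation_params()) {
  if (!inherits(params, "segregation_params")) {
    stop("params must be created with segregation_params()")
  }
  f <- params$carrier_gamete_fusion_fraction
  b <- params$baseline_proximal_fraction
  proximal <- f + (1 - f) * b
  c(proximal = proximal, distant = 1 - proximal)
}

#' Write / read a karyotype as JSON
#'
#' Serialises the chromosome table together with the fusion flag and
#' gonosome identity. The round trip is lossless.
#'
#' @param k a `karyotype`.
#' @param path file path.
#' @return `write_karyotype_json` returns `path` invisibly;
#'   `read_karyotype_json` returns a `karyotype`.
#' @export
write_karyotype_json <- function(k, path) {
  stopifnot(inherits(k, "karyotype"))
  jsonlite::write_json(
    list(chromosomes = k$chromosomes,
         is_fused_13_17 = k$is_fused_13_17,
         gonosome = k$gonosome),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_karyotype_json
#' @export
read_karyotype_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- list(
    chromosomes = data.frame(name = raw$chromosomes$name,
                             centromere_class = raw$chromosomes$centromere_class,
                             telomere_count = as.integer(raw$chromosomes$telomere_count),
                             stringsAsFactors = FALSE),
    is_fused_13_17 = isTRUE(raw$is_fused_13_17),
    gonosome = raw$gonosome
  )
  class(k) <- "karyotype"
  k
}
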