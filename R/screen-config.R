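#' Configuration for the CA screening cascade
#'
#' Collects every threshold used by the two-branch candidate screen.  The
#' defaults mirror the published mining campaign: a curated set of CA-related
#' Pfam profiles (the "SCAP" set) drives the domain-evidence branch; proteins
#' without any SCAP hit fall through to a similarity branch against a
#' keyword-filtered reference ("fnr") with an inclusive e-value cutoff of
#' 1e-50.  Candidates are then checked for the beta-CA active-site motifs
#' CxDxR and HxxC, valid start/stop codons on their source genes, plausible
#' length relative to the CA family mean, sampling-site environment
#' (temperature at or above `min_temperature`, alkaline pH), and mutual
#' sequence identity below `identity_cutoff`.
#'
#' @param scap_accessions versioned Pfam accessions forming the domain branch.
#' @param fnr_keywords keywords used to build/filter the similarity reference;
#'   multi-word phrases match as substrings on word boundaries, single words
#'   as whole tokens (so `"ca"` does not match "calcium").
#' @param evalue_cutoff inclusive similarity-branch e-value threshold.
#' @param identity_cutoff percent identity at or above which two candidates
#'   are considered redundant (inclusive).
#' @param min_temperature minimum sampling temperature in degrees C.  The
#'   published campaign screened samples at >= 80 degrees C and shortlisted at
#'   >= 90 degrees C.
#' @param require_alkaline require sample pH > 7.
#' @param motifs active-site patterns; `x` is a single-residue wildcard.
#' @param start_codons,stop_codons accepted gene boundary codons.
#' @param family_mean_length mean CA family length (residues) used by the
#'   length check.
#' @param length_window multiplicative window `c(low, high)` around
#'   `family_mean_length` within which candidate lengths must fall.
#' @param sp_tm_policy `"flag"` records signal-peptide/transmembrane calls as
#'   reasons without rejecting; `"reject"` excludes flagged proteins.
#' @return A list of class `"screen_config"`.
#' @export
#' @examples
#' cfg <- screen_config(min_temperature = 90)
#' cfg$evalue_cutoff
screen_config <- function(scap_accessions = c(
                            "PF00194.23", "PF00484.21", "PF00101.22",
                            "PF08936.12", "PF00016.22", "PF02788.18",
                            "PF00936.21", "PF03319.15"
                          ),
                          fnr_keywords = c(
                            "carbonic anhydrase",
                            "carbonic dehydratase", "ca"
                          ),
                          evalue_cutoff = 1e-50,
                          identity_cutoff = 90,
                          min_temperature = 80,
                          require_alkaline = TRUE,
                          motifs = c("CxDxR", "HxxC"),
                          start_codons = c("ATG", "GTG", "TTG"),
                          stop_codons = c("TAA", "TGA", "TAG"),
                          family_mean_length = 180,
                          length_window = c(0.5, 2),
                          sp_tm_policy = c("flag", "reject")) {
  sp_tm_policy <- match.arg(sp_tm_policy)
  stopifnot(
    evalue_cutoff > 0, identity_cutoff > 0, identity_cutoff <= 100,
    is.finite(min_temperature), length(length_window) == 2,
    length_window[1] < length_window[2], family_mean_length > 0,
    length(motifs) >= 1, length(fnr_keywords) >= 1
  )
  structure(
    list(
      scap_accessions = scap_accessions,
      fnr_keywords = fnr_keywords,
      evalue_cutoff = evalue_cutoff,
      identity_cutoff = identity_cutoff,
      min_temperature = min_temperature,
      require_alkaline = require_alkaline,
      motifs = motifs,
      start_codons = toupper(start_codons),
      stop_codons = toupper(stop_codons),
      family_mean_length = family_mean_length,
      length_window = length_window,
      sp_tm_policy = sp_tm_policy
    ),
    class = "screen_config"
  )
}
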