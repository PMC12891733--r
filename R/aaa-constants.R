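# Shared vocabularies, loaded before every other file.

#' Study condition labels
#'
#' The fixed vocabulary of sample conditions: the pre-vaccine unstimulated
#' baseline, the vehicle-only (DMSO/IL-2) culture, the irrelevant control
#' peptide culture, the six mutant-KRAS peptide expansion cultures, and
#' resected/biopsied tumor tissue.
#'
#' @format Character vector of length 10.
#' @export
CONDITIONS <- c("baseline", "vehicle_only", "control_peptide",
                "G12V", "G12A", "G12R", "G12C", "G12D", "G13D",
                "tumor_tissue")

#' The six mutant-KRAS vaccine antigens
#' @format Character vector of length 6.
#' @export
MKRAS_ANTIGENS <- c("G12V", "G12A", "G12R", "G12C", "G12D", "G13D")

# amino-acid alphabet used to validate CDR3 sequences
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
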