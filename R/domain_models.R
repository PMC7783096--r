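#' Construct a domain model
#'
#' A domain model is the unit consumed by [scan_domains()] and by the
#' proteome generator: a token label, a consensus amino-acid sequence,
#' and the minimum fraction of identical positions required to call a
#' hit against that consensus.
#'
#' @param name token label; one of `SP`, `LRR`, `MD`, `PK`, `Kin`,
#'   `TMD`, `CC`.  `MLD` is deliberately absent: a malectin-like domain
#'   is represented as two tandem `MD` hits and collapsed downstream.
#' @param consensus amino-acid string, length >= 10.
#' @param min_identity fraction in `[0, 1]`; hits below it are dropped.
#' @return object of class `domain_model`.
#' @export
#' @examples
#' m <- domain_model("MD", strrep("ACDEFGHIKL", 3), 0.7)
#' m$name
domain_model <- function(name, consensus, min_identity = 0.6) {
  if (!is.character(name) || length(name) != 1L || !(name %in% .SCAN_TOKENS))
    stop("unknown domain token '", name, "'; expected one of: ",
         paste(.SCAN_TOKENS, collapse = ", "))
  consensus <- toupper(consensus)
  if (nchar(consensus) < 10L)
    stop("consensus for '", name, "' must be at least 10 residues")
  if (!grepl("^[A-Z]+$", consensus))
    stop("consensus for '", name, "' contains non-letter characters")
  if (!is.numeric(min_identity) || min_identity < 0 || min_identity > 1)
    stop("min_identity must lie in [0, 1]")
  structure(list(name = name, consensus = consensus,
                 min_identity = min_identity),
            class = "domain_model")
}

#' @export
print.domain_model <- function(x, ...) {
  cat(sprintf("<domain_model %s: %d aa, min identity %.2f>\n",
              x$name, nchar(x$consensus), x$min_identity))
  invisible(x)
}

# Fixed consensus sequences for the built-in models.  MD/PK/Kin are
# arbitrary but fixed strings long enough that random background never
# reaches the identity threshold; SP/TMD are hydrophobic-styled and CC
# heptad-styled purely for readability of generated proteins.
.CONSENSI <- c(
  MD  = paste0("TFALEVTRHEFQYVRDKEFPFYCIDALMRIEEVPFECVDTVGGCYDCGLIFATHEPLKN",
               "YKMDSFQFCVTVFQIIEEHLVPWSTNKMSIGAPQFKSMLLAWTQQRGRMFSTTVCGGGY"),
  LRR = "LSGLNLSGNKLSGSIPDLSNLKSLQVLDLSNNSLSGPIPSLANLTNLE",
  PK  = paste0("YTYEYMTKTPTYATACISDFPNAWFRGSLHKKDVRRYSAGMKYPFMRCGAQSTMVCLEY",
               "RHTFYVKMGLKWKMWELTNGRKLVHQNWLFCDCQSEG"),
  Kin = paste0("QAEPGNHNFVHPCDARYMKLHWVNLKWRQDYLCTVWQTLFPVWWLSCEHAQYWNWGNLH",
               "WCGKMGFQLRAKLTNAMEDGFLYCEYKQQDVLAIYFG"),
  TMD = "LLVLLIAVLGVIFLAVLAILLWKR",
  SP  = "MKTLLSLALLLLAVSSAQAFSPAA",
  CC  = "LEALKQKLEALKQKLEALKQKLEALKQK"
)

#' Built-in domain models
#'
#' Fixed consensus models for the seven scanned tokens, shared by the
#' synthetic proteome generator and the scanner so that planted domains
#' are recoverable by construction.
#'
#' @param min_identity identity threshold applied to every model.
#' @return named list of [domain_model()] objects.
#' @export
default_domain_models <- function(min_identity = 0.6) {
  lapply(stats::setNames(nm = names(.CONSENSI)), function(tok)
    domain_model(tok, .CONSENSI[[tok]], min_identity))
}
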