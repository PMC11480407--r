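#' @include AllClasses.R
NULL

#' Construct a wobble rule set
#'
#' @param rules Named list mapping wobble keys (position-34 base or
#'   modification label) to character vectors of readable codon
#'   third-position bases.
#' @param version Label for the table.
#' @return A [WobbleRuleSet-class].
#' @examples
#' wobbleRuleSet(list(G = c("C", "U"), C = "G"), version = "toy")
#' @export
wobbleRuleSet <- function(rules, version = "custom") {
    new("WobbleRuleSet", rules = lapply(rules, as.character),
        version = as.character(version))
}

#' Default bacterial wobble decoding rules
#'
#' The package's default position-34 reading table for E. coli:
#' unmodified G34 reads codon-3 C/U, C34 reads G, A34 reads U, and
#' unmodified U34 reads A/G (the conservative two-out reading used in
#' split codon boxes). Modified wobble bases: cmo5U and mcmo5U
#' (uridine-5-oxyacetic acid and its methyl ester, found in the
#' family-box Ala/Val/Pro/Thr/Ser/Leu-UAG isoacceptors) read all four
#' bases; mnm5U-type (5-methylaminomethyl(-2-thio)uridine) reads A/G;
#' inosine (I, deaminated A34 of the ArgQZYV tRNAs) reads A/C/U and --
#' as required for the CGG codon to remain covered when argX alone cannot
#' -- also G (four-way inosine wobble, observed in vivo); lysidine (k2C,
#' tRNA-Ile2) reads only A, switching CAU specificity from AUG to AUA;
#' ac4C (elongator tRNA-Met) reads only G; queuosine (Q, Tyr/His/Asn/Asp
#' tRNAs) reads C/U.
#'
#' The table ships as a YAML file and can be edited and reloaded with
#' [readWobbleRules()].
#'
#' @return A [WobbleRuleSet-class].
#' @examples
#' defaultWobbleRules()
#' @export
defaultWobbleRules <- function() {
    if (is.null(.codeEnv$defaultRules)) {
        path <- system.file("extdata", "wobble_rules.yaml",
                            package = "tRNAessentials", mustWork = TRUE)
        .codeEnv$defaultRules <- readWobbleRules(path)
    }
    .codeEnv$defaultRules
}

#' Read / write a wobble rule table (YAML)
#'
#' The on-disk format is a flat YAML mapping with a `version` string and a
#' `rules` block of key -> base-list entries. `writeWobbleRules()` followed
#' by `readWobbleRules()` is the identity, and re-writing a loaded file
#' reproduces it byte for byte (keys and bases keep their order).
#'
#' @param path File path.
#' @param ruleset A [WobbleRuleSet-class].
#' @return `readWobbleRules()` a [WobbleRuleSet-class];
#'   `writeWobbleRules()` the path, invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeWobbleRules(defaultWobbleRules(), f)
#' identical(rules(readWobbleRules(f)), rules(defaultWobbleRules()))
#' @export
readWobbleRules <- function(path) {
    if (!file.exists(path))
        stop("wobble rule file not found: ", path, call. = FALSE)
    y <- yaml::read_yaml(path)
    if (is.null(y$rules) || is.null(y$version))
        stop("wobble rule file needs 'version' and 'rules' blocks: ", path,
             call. = FALSE)
    wobbleRuleSet(y$rules, version = y$version)
}

#' @rdname readWobbleRules
#' @export
writeWobbleRules <- function(ruleset, path) {
    stopifnot(is(ruleset, "WobbleRuleSet"))
    y <- list(version = ruleset@version,
              rules = lapply(ruleset@rules, as.list))
    # as.list per rule forces YAML block sequences, matching the shipped file
    yaml::write_yaml(y, path)
    invisible(path)
}
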