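# Scaffold-based chemical classification. Each psychoactive is assigned to
# a class by substructure (subgraph) matching against parent-molecule
# SMARTS patterns, highest-priority match first. The default rule set is a
# reconstruction of the standard parent scaffolds: the cathinone rule
# (beta-keto-phenethylamine) outranks amphetamine (alpha-methyl-
# phenethylamine), which outranks the bare phenethylamine chain; tryptamine
# is 3-(2-aminoethyl)indole; cannabinoids are caught by either the
# gem-dimethyl benzochromene core (THC/cannabinol type) or the
# alkyl-resorcinol + carbocycle motif (cannabidiol type). Molecules
# matching no rule fall back to "other".

#' Default scaffold rule set
#'
#' @return data.frame `(class_label, pattern, priority)`; higher priority
#'   wins. User-editable: pass a modified copy (or [read_scaffold_rules()]
#'   output) to the classifiers.
#' @export
default_scaffold_rules <- function() {
  rules <- data.frame(
    class_label = c("cathinone", "amphetamine", "cannabinoid", "cannabinoid",
                    "tryptamine", "phenethylamine"),
    pattern = c("cC(=O)C(C)N",                      # beta-keto + alpha-methyl amine on an aryl
                "c1ccccc1CC(C)N",                   # alpha-methyl phenethylamine
                "CC1(C)Oc2ccccc2~[#6]~[#6]~1",      # gem-dimethyl benzochromene core
                "C(CCC)c1cc(O)c(~[#6;!c])c(O)c1",   # alkyl resorcinol + carbon substituent
                "c1cc2c(cc1)[nH]cc2CCN",            # 3-(2-aminoethyl)indole
                "c1ccccc1CCN"),                     # parent phenethylamine chain
    priority = c(60L, 50L, 40L, 39L, 30L, 20L),
    stringsAsFactors = FALSE
  )
  validate_scaffold_rules(rules)
}

validate_scaffold_rules <- function(rules) {
  need <- c("class_label", "pattern", "priority")
  miss <- setdiff(need, names(rules))
  if (length(miss)) stop("scaffold rules lack column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(rules$priority)) {
    stop("scaffold rule priorities must be unique", call. = FALSE)
  }
  bad <- setdiff(unique(rules$class_label), setdiff(CHEM_CLASSES, "none"))
  if (length(bad)) stop("unknown class label(s) in rules: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  rules[order(-rules$priority), , drop = FALSE]
}

#' Read a scaffold rule file
#'
#' @param path TSV with columns `class_label`, `pattern`, `priority`, or a
#'   YAML list of records with those fields.
#' @return validated rules data.frame, highest priority first.
#' @export
read_scaffold_rules <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    y <- yaml::read_yaml(path)
    rules <- do.call(rbind, lapply(y, as.data.frame))
  } else {
    rules <- utils::read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE, quote = "",
                               comment.char = "")
  }
  rules$priority <- as.integer(rules$priority)
  validate_scaffold_rules(rules)
}

# SMILES -> single-molecule SDF, NULL when the molecule has no bond block
# (single atoms cannot carry a multi-atom scaffold), error on unparseable
# input.
smiles_to_sdf <- function(smiles, id = "query") {
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, id))),
    error = function(e) stop("unparseable structure '", smiles, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!any(ChemmineR::validSDF(sdf))) return(NULL)
  sdf
}

matches_pattern <- function(sdf, pattern) {
  hits <- tryCatch(
    ChemmineR::smartsSearchOB(sdf, pattern, uniqueMatches = FALSE),
    error = function(e) stop("SMARTS match failed for pattern '", pattern, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  any(hits > 0)
}

#' Classify a single structure by scaffold substructure matching
#'
#' @param smiles structure string (must parse; an unparseable string is an
#'   error naming the input).
#' @param rules scaffold rules (default [default_scaffold_rules()]).
#' @return the class label of the highest-priority rule whose pattern is a
#'   subgraph of the molecule, or `"other"` when none match.
#' @examples
#' \donttest{
#' classify_smiles("NCCc1ccccc1") # "phenethylamine"
#' }
#' @export
classify_smiles <- function(smiles, rules = default_scaffold_rules()) {
  stopifnot(length(smiles) == 1L, is.character(smiles), nzchar(smiles))
  rules <- validate_scaffold_rules(rules)
  sdf <- smiles_to_sdf(smiles)
  if (is.null(sdf)) return("other")
  for (i in seq_len(nrow(rules))) {
    if (matches_pattern(sdf, rules$pattern[i])) return(rules$class_label[i])
  }
  "other"
}

#' Classify a compound library by scaffold substructure matching
#'
#' Fills `chem_class` for every psychoactive record carrying a SMILES;
#' records without structures (or non-psychoactives) are left untouched.
#' Per-compound parse failures are collected, not fatal.
#'
#' @param compounds a [compound_table()].
#' @param rules scaffold rules.
#' @return list with `compounds` (updated table), `tally` (named count per
#'   class over the newly classified records) and `failures` (data.frame
#'   of compound_id / error message).
#' @export
classify_library <- function(compounds, rules = default_scaffold_rules()) {
  rules <- validate_scaffold_rules(rules)
  idx <- which(compounds$is_psychoactive & !is.na(compounds$smiles) &
                 nzchar(compounds$smiles))
  failures <- data.frame(compound_id = character(), error = character(),
                         stringsAsFactors = FALSE)
  for (i in idx) {
    cls <- tryCatch(classify_smiles(compounds$smiles[i], rules),
                    error = function(e) e)
    if (inherits(cls, "error")) {
      failures <- rbind(failures,
                        data.frame(compound_id = compounds$compound_id[i],
                                   error = conditionMessage(cls),
                                   stringsAsFactors = FALSE))
    } else {
      compounds$chem_class[i] <- cls
    }
  }
  done <- setdiff(idx, match(failures$compound_id, compounds$compound_id))
  tally <- table(factor(compounds$chem_class[done],
                        levels = setdiff(CHEM_CLASSES, "none")))
  list(compounds = compounds, tally = c(tally), failures = failures)
}
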