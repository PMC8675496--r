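# Coding-system primitives: ATC and ICD-10 parsing, normalization, and
# prefix-based group membership. Every rule in the knowledge base resolves
# drugs and health problems through these functions.

# Expected character class per position of a 7-character ATC code:
# letter / digit / digit / letter / letter / digit / digit.
.atc_char_class <- c("letter", "digit", "digit", "letter", "letter", "digit", "digit")

#' Parse and normalize an ATC code
#'
#' ATC (Anatomical Therapeutic Chemical) codes are hierarchical with five
#' levels, written as strings of length 1, 3, 4, 5 or 7. Normalization is
#' uppercasing plus whitespace trimming and is idempotent.
#'
#' @param text a single character string at any ATC level, case-insensitive
#' @return the normalized uppercase code (plain character scalar)
#' @export
parse_atc <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    abort_fmt("ATC code must be a single non-empty string")
  code <- toupper(trimws(text))
  n <- nchar(code)
  if (!n %in% c(1L, 3L, 4L, 5L, 7L))
    abort_fmt("malformed ATC code '%s': length %d is not one of 1, 3, 4, 5, 7", code, n)
  chars <- strsplit(code, "", fixed = TRUE)[[1]]
  for (i in seq_len(n)) {
    want <- .atc_char_class[i]
    ok <- if (want == "letter") grepl("^[A-Z]$", chars[i]) else grepl("^[0-9]$", chars[i])
    if (!ok)
      abort_fmt("malformed ATC code '%s': expected a %s at position %d", code, want, i)
  }
  code
}

#' ATC hierarchy level (1-5) of a normalized code
#' @export
atc_level <- function(code) {
  code <- parse_atc(code)
  match(nchar(code), c(1L, 3L, 4L, 5L, 7L))
}

#' Parse and normalize an ICD-10 code
#'
#' Normal form is a letter, two digits, and an optional dot-separated
#' extension ("N18", "N18.3"). An undotted extension ("N183") gains the dot,
#' so normalization is idempotent and the 3-character category is always
#' `substr(code, 1, 3)`.
#'
#' @export
parse_icd10 <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    abort_fmt("ICD-10 code must be a single non-empty string")
  code <- toupper(gsub("[[:space:]]", "", text))
  if (nchar(code) > 3L && substr(code, 4L, 4L) != ".")
    code <- paste0(substr(code, 1L, 3L), ".", substr(code, 4L, nchar(code)))
  if (!grepl("^[A-Z][0-9]{2}(\\.[0-9A-Z]{1,4})?$", code))
    abort_fmt("malformed ICD-10 code '%s': expected letter + 2 digits + optional '.ext'", code)
  code
}

#' ICD-10 three-character category of a code
#' @export
icd10_category <- function(code) substr(parse_icd10(code), 1L, 3L)

#' Construct a drug group
#'
#' A drug group names a set of products either by ATC prefixes (includes
#' minus excludes) or by explicit member ingredient ids, or both. Prefixes
#' may sit at any ATC level, so a group can target a whole anatomical class
#' or a single substance.
#'
#' @param group_id,label identifiers
#' @param include_prefixes,exclude_prefixes character vectors of ATC prefixes
#' @param member_ingredients character vector of ingredient ids
#' @export
drug_group <- function(group_id, label = group_id,
                       include_prefixes = character(0),
                       exclude_prefixes = character(0),
                       member_ingredients = character(0)) {
  if (!nzchar(group_id)) abort_fmt("drug group needs a non-empty group_id")
  include_prefixes <- vapply(include_prefixes, parse_atc, character(1), USE.NAMES = FALSE)
  exclude_prefixes <- vapply(exclude_prefixes, parse_atc, character(1), USE.NAMES = FALSE)
  if (length(include_prefixes) == 0L && length(member_ingredients) == 0L)
    abort_fmt("drug group '%s': include_prefixes must be non-empty unless member_ingredients is non-empty",
              group_id)
  structure(list(group_id = group_id, label = label,
                 include_prefixes = include_prefixes,
                 exclude_prefixes = exclude_prefixes,
                 member_ingredients = as.character(member_ingredients)),
            class = "drug_group")
}

#' Construct a health-problem group (set of ICD-10 prefixes)
#'
#' Prefixes must be at the 3-character category boundary or longer; matching
#' respects code-unit boundaries ("I10" matches "I10" and "I10.9", never
#' "I11.0").
#' @export
problem_group <- function(group_id, label = group_id, include_prefixes) {
  if (!nzchar(group_id)) abort_fmt("problem group needs a non-empty group_id")
  if (length(include_prefixes) == 0L)
    abort_fmt("problem group '%s': include_prefixes must be non-empty", group_id)
  include_prefixes <- vapply(include_prefixes, parse_icd10, character(1), USE.NAMES = FALSE)
  structure(list(group_id = group_id, label = label,
                 include_prefixes = include_prefixes),
            class = "problem_group")
}

#' Is an ATC code in a drug group (prefix semantics only)?
#'
#' TRUE iff the normalized code starts with at least one include prefix and
#' with no exclude prefix. Ingredient-level membership of combination
#' products is handled by [product_in_group()].
#' @export
atc_in_group <- function(code, group) {
  stopifnot(inherits(group, "drug_group"))
  code <- parse_atc(code)
  inc <- any(startsWith(code, group$include_prefixes))
  exc <- any(startsWith(code, group$exclude_prefixes))
  inc && !exc
}

#' Is an ICD-10 code in a health-problem group?
#' @export
icd10_in_group <- function(code, group) {
  stopifnot(inherits(group, "problem_group"))
  code <- parse_icd10(code)
  any(startsWith(code, group$include_prefixes))
}

#' Construct a prescribable product
#'
#' Fixed combinations carry one (combination-level) ATC code and all
#' constituent ingredient ids; mono-products carry a singleton ingredient
#' set.
#' @export
product <- function(product_id, label = product_id, atc, ingredients) {
  if (!nzchar(product_id)) abort_fmt("product needs a non-empty product_id")
  ingredients <- as.character(ingredients)
  if (length(ingredients) == 0L)
    abort_fmt("product '%s': ingredients must be non-empty", product_id)
  structure(list(product_id = product_id, label = label,
                 atc = parse_atc(atc), ingredients = ingredients),
            class = "product")
}

#' Constituent ingredient ids of a product
#' @export
product_ingredients <- function(product) {
  stopifnot(inherits(product, "product"))
  product$ingredients
}

#' Is a product in a drug group?
#'
#' A product belongs to a group if its ATC code matches the group's prefix
#' rules, or any of its ingredients is listed as an explicit member. This is
#' the attribution path through which a fixed combination (e.g. tramadol
#' with paracetamol) triggers rules written against one of its components.
#' @export
product_in_group <- function(product, group) {
  stopifnot(inherits(product, "product"), inherits(group, "drug_group"))
  atc_in_group(product$atc, group) ||
    any(product$ingredients %in% group$member_ingredients)
}

# Can a bare ingredient id be resolved into a drug group? Used for
# hypersensitivity/ADR targets recorded at ingredient level: the ingredient
# matches via explicit membership or via any formulary product that contains
# it and falls in the group.
ingredient_in_group <- function(ingredient, group, formulary) {
  if (ingredient %in% group$member_ingredients) return(TRUE)
  for (p in formulary) {
    if (ingredient %in% p$ingredients && product_in_group(p, group)) return(TRUE)
  }
  FALSE
}

#' Read a formulary CSV
#'
#' Columns: product_id, label, atc, ingredients (";"-separated). Returns a
#' named list of [product()] objects keyed by product_id.
#' @export
read_formulary <- function(path) {
  df <- require_columns(read_csv_strict(path),
                        c("product_id", "label", "atc", "ingredients"), path)
  if (anyDuplicated(df$product_id))
    abort_fmt("%s: duplicate product_id(s): %s", path,
              paste(unique(df$product_id[duplicated(df$product_id)]), collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    product(df$product_id[i], df$label[i], df$atc[i], split_list_field(df$ingredients[i])))
  names(out) <- df$product_id
  structure(out, class = "formulary")
}

#' Write a formulary back to CSV (round-trip inverse of [read_formulary()])
#' @export
write_formulary <- function(formulary, path) {
  df <- data.frame(
    product_id = vapply(formulary, `[[`, character(1), "product_id"),
    label = vapply(formulary, `[[`, character(1), "label"),
    atc = vapply(formulary, `[[`, character(1), "atc"),
    ingredients = vapply(formulary, function(p) join_list_field(p$ingredients), character(1)),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
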