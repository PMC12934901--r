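# Annotation schema: entity categories, relation types, polarity machinery.

KG_POLARITIES <- c("beneficial", "harmful", "neutral")

KG_RELATION_TYPES <- c(
  "associated_with", "affects", "causes", "regulates", "modifies",
  "maintains", "assists", "benefits", "increases", "reduces",
  "inhibits", "harms"
)

# Default class membership of the twelve relation types: benefits/increases
# carry beneficial polarity, reduces/inhibits/harms harmful, the rest are
# neutral/observational. Individual relation instances may override this
# through an explicit polarity attribute.
KG_TYPE_POLARITY <- c(
  associated_with = "neutral", affects = "neutral", causes = "neutral",
  regulates = "neutral", modifies = "neutral", maintains = "neutral",
  assists = "neutral", benefits = "beneficial", increases = "beneficial",
  reduces = "harmful", inhibits = "harmful", harms = "harmful"
)

KG_DEFAULT_CATEGORIES <- c(
  "nutrition", "microbiome", "metabolite", "gene", "protein",
  "physiological_process", "clinical_outcome", "disease", "population",
  "intervention", "biomarker"
)

#' Polarity multipliers for edge weighting
#'
#' The polarity multiplier P scales the evidence weight of an edge:
#' 1.2 for beneficial, 1.1 for harmful, 1.0 for neutral relationships.
#'
#' @param beneficial,harmful,neutral Strictly positive multipliers.
#' @return Named numeric vector of class `kg_polarity_weights`.
#' @examples
#' polarity_weights()
#' @export
polarity_weights <- function(beneficial = 1.2, harmful = 1.1, neutral = 1.0) {
  pw <- c(beneficial = beneficial, harmful = harmful, neutral = neutral)
  if (any(!is.finite(pw)) || any(pw <= 0)) {
    abort("polarity multipliers must be strictly positive and finite")
  }
  structure(pw, class = c("kg_polarity_weights", "numeric"))
}

#' Annotation schema configuration
#'
#' Bundles the entity-category vocabulary, the twelve directional relation
#' types, the default relation-type-to-polarity mapping, and the polarity
#' multipliers used by the edge-weighting function.
#'
#' The eleven default categories are configuration, not ground truth: the
#' category vocabulary of an annotation project is whatever its guideline
#' defines, and any list can be supplied.
#'
#' @param categories Character vector of entity category ids.
#' @param relation_types Character vector of relation type ids
#'   (default: the twelve standard types).
#' @param type_to_polarity Named character vector mapping each relation type
#'   to its default polarity class.
#' @param multipliers A [polarity_weights()] object.
#' @return A `kg_schema` list.
#' @examples
#' sc <- kg_schema()
#' sc$relation_types
#' @export
kg_schema <- function(categories = KG_DEFAULT_CATEGORIES,
                      relation_types = KG_RELATION_TYPES,
                      type_to_polarity = KG_TYPE_POLARITY,
                      multipliers = polarity_weights()) {
  categories <- as.character(categories)
  relation_types <- as.character(relation_types)
  if (anyDuplicated(categories)) abort("duplicate category ids")
  if (anyDuplicated(relation_types)) abort("duplicate relation type ids")
  missing_map <- setdiff(relation_types, names(type_to_polarity))
  if (length(missing_map) > 0) {
    abort(paste0(
      "relation types without a default polarity: ",
      paste(missing_map, collapse = ", ")
    ))
  }
  bad_pol <- setdiff(unname(type_to_polarity), KG_POLARITIES)
  if (length(bad_pol) > 0) {
    abort(paste0("unknown polarity class: ", paste(bad_pol, collapse = ", ")))
  }
  if (!inherits(multipliers, "kg_polarity_weights")) {
    multipliers <- do.call(polarity_weights, as.list(multipliers))
  }
  structure(
    list(
      categories = categories,
      relation_types = relation_types,
      type_to_polarity = type_to_polarity[relation_types],
      multipliers = multipliers
    ),
    class = "kg_schema"
  )
}

#' Read a schema configuration from YAML
#'
#' The YAML file may define `categories`, `relation_types`,
#' `type_to_polarity` (a mapping) and `multipliers` (a mapping with keys
#' beneficial/harmful/neutral); omitted fields fall back to the defaults.
#'
#' @param path Path to a YAML file.
#' @return A `kg_schema`.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) abort(paste0("schema file not found: ", path))
  raw <- yaml::read_yaml(path)
  kg_schema(
    categories = raw$categories %||% KG_DEFAULT_CATEGORIES,
    relation_types = raw$relation_types %||% KG_RELATION_TYPES,
    type_to_polarity = unlist(raw$type_to_polarity) %0% KG_TYPE_POLARITY,
    multipliers = if (is.null(raw$multipliers)) polarity_weights() else
      do.call(polarity_weights, raw$multipliers)
  )
}

#' @export
print.kg_schema <- function(x, ...) {
  cat("<kg_schema>\n")
  cat("  categories:    ", length(x$categories), "\n")
  cat("  relation types:", length(x$relation_types), "\n")
  cat("  multipliers:   ",
      paste(names(x$multipliers), unname(x$multipliers),
            sep = "=", collapse = " "), "\n")
  invisible(x)
}

default_polarity <- function(relation_type, schema) {
  unname(schema$type_to_polarity[relation_type])
}
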