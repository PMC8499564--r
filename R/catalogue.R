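# Healthcare-service catalogues: services with ICF-coded treatment targets.

SERVICE_CATEGORIES <- c("medical", "social_care", "assistive_product")

new_catalogue <- function(services, name = NA_character_, version = NA_character_) {
  structure(
    services,
    catalogue_name = name,
    catalogue_version = version,
    class = c("service_catalogue", class(services))
  )
}

#' Load a service catalogue
#'
#' Reads the catalogue JSON schema
#' `{"name":..., "version":..., "services":[{"id","name","category",
#' "targets":["d450",...],"description"}]}` and validates it: ids unique,
#' every service with a nonempty target set, all targets parseable ICF
#' codes present in the active taxonomy, categories one of `medical`,
#' `social_care`, `assistive_product`. All offending services are listed
#' in a single validation error.
#'
#' @param path Path to a catalogue JSON file.
#' @param taxonomy Optional [icf_taxonomy()] to validate targets against.
#' @return A tibble of class `service_catalogue` (columns `id`, `name`,
#'   `category`, `targets` list-column, `description`), ordered by id,
#'   with catalogue name/version as attributes.
#' @examples
#' cat <- demo_catalogue()
#' dplyr::filter(cat, id == "walking_frame")$targets
#' @export
read_catalogue <- function(path, taxonomy = NULL) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  services <- purrr::map_dfr(obj$services, function(s) {
    tibble::tibble(
      id = as.character(s$id),
      name = as.character(s$name),
      category = as.character(s$category),
      targets = list(sort(unique(as.character(unlist(s$targets))))),
      description = if (is.null(s$description)) NA_character_ else as.character(s$description)
    )
  })
  if (nrow(services) == 0) {
    services <- tibble::tibble(
      id = character(), name = character(), category = character(),
      targets = list(), description = character()
    )
  }
  validate_catalogue(
    new_catalogue(services, name = obj$name, version = obj$version),
    taxonomy = taxonomy
  )
}

#' @rdname read_catalogue
#' @param catalogue A `service_catalogue` to validate.
#' @export
validate_catalogue <- function(catalogue, taxonomy = NULL) {
  problems <- character()
  dup <- unique(catalogue$id[duplicated(catalogue$id)])
  if (length(dup) > 0) {
    problems <- c(problems, sprintf("duplicate service id(s): %s",
                                    paste(dup, collapse = ", ")))
  }
  empty <- catalogue$id[vapply(catalogue$targets, length, integer(1)) == 0]
  if (length(empty) > 0) {
    problems <- c(problems, sprintf("service(s) with empty targets: %s",
                                    paste(empty, collapse = ", ")))
  }
  bad_cat <- catalogue$id[!catalogue$category %in% SERVICE_CATEGORIES]
  if (length(bad_cat) > 0) {
    problems <- c(problems, sprintf("service(s) with unknown category: %s",
                                    paste(bad_cat, collapse = ", ")))
  }
  for (i in seq_len(nrow(catalogue))) {
    tgt <- catalogue$targets[[i]]
    if (length(tgt) == 0) next
    ok <- icf_is_valid(tgt)
    if (!all(ok)) {
      problems <- c(problems, sprintf("service '%s' has invalid ICF target(s): %s",
                                      catalogue$id[i],
                                      paste(tgt[!ok], collapse = ", ")))
    } else if (!is.null(taxonomy)) {
      miss <- setdiff(tgt, taxonomy$code)
      if (length(miss) > 0) {
        problems <- c(problems, sprintf("service '%s' has target(s) outside the taxonomy: %s",
                                        catalogue$id[i],
                                        paste(miss, collapse = ", ")))
      }
    }
  }
  if (length(problems) > 0) {
    rlang::abort(
      paste0("Invalid service catalogue:\n",
             paste0("- ", problems, collapse = "\n")),
      class = "icfmatch_validation_error"
    )
  }
  out <- dplyr::arrange(tibble::as_tibble(catalogue), .data$id)
  new_catalogue(out,
                name = attr(catalogue, "catalogue_name"),
                version = attr(catalogue, "catalogue_version"))
}

#' @rdname read_catalogue
#' @export
write_catalogue <- function(catalogue, path) {
  catalogue <- validate_catalogue(catalogue)
  obj <- list(
    name = attr(catalogue, "catalogue_name"),
    version = attr(catalogue, "catalogue_version"),
    services = purrr::pmap(
      list(catalogue$id, catalogue$name, catalogue$category,
           catalogue$targets, catalogue$description),
      function(id, name, category, targets, description) {
        s <- list(id = id, name = name, category = category,
                  targets = as.list(sort(targets)))
        if (!is.na(description)) s$description <- description
        s
      }
    )
  )
  if (is.null(obj$name) || is.na(obj$name)) obj$name <- NULL
  if (is.null(obj$version) || is.na(obj$version)) obj$version <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Bundled demonstration catalogue
#'
#' A curated catalogue of about twenty-five medical, social-care and
#' assistive-product services for older multimorbid patients (walker
#' training, housekeeping help, occupational therapy, nursing service,
#' personal emergency response system, meals on wheels, audiologist, ...).
#' The ICF treatment-target assignments are the implementers' curation,
#' documented in the catalogue file itself; they illustrate the matching
#' mechanics and are not a clinically validated linkage.
#'
#' @param taxonomy Taxonomy to validate against; defaults to the bundled
#'   subset.
#' @return A `service_catalogue` tibble.
#' @export
demo_catalogue <- function(taxonomy = icf_taxonomy()) {
  read_catalogue(
    system.file("extdata", "services.json", package = "icfmatch"),
    taxonomy = taxonomy
  )
}
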