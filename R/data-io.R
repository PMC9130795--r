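#' Assemble and validate a study dataset
#'
#' A study dataset bundles every table the pipeline consumes: the individual
#' register, daily census, party contact sessions, focal observation time,
#' social events, male-male coalitions and (optionally) microsatellite
#' genotypes. All downstream stages take this bundle as their first argument.
#'
#' Validation enforces the documented schemas and the referential integrity of
#' identifiers: every id referenced by census, focal, event, coalition or
#' genotype rows must exist in `individuals`.
#'
#' @param individuals tibble with columns `id`, `sex` ("male"/"female"),
#'   `party`, `birth_date` (Date, may be `NA`), `mother_id` (may be `NA`).
#' @param census tibble with `date`, `individual_id`, `party`, `present`
#'   (logical) and optional `repro_state`; at most one row per individual-date.
#' @param sessions tibble with `date`, `party`, `duration_h` (> 0). Several
#'   sessions on one day are allowed and are summed.
#' @param events tibble with `timestamp` (UTC), `actor_id`, `receiver_id`,
#'   `behaviour` (one of `r paste(baboonbonds_behaviours(), collapse = ", ")`),
#'   `duration_s` (0 for point events), `source` ("focal"/"adlib") and
#'   `focal_id` (`NA` for ad libitum records).
#' @param coalitions tibble with `timestamp`, `ally1_id`, `ally2_id`,
#'   `target_id`, `source`; allies are stored in canonical order.
#' @param genotypes optional long tibble with `individual_id`, `locus`,
#'   `allele1`, `allele2` (integer allele codes, `NA` = missing).
#' @param focals optional tibble with `date`, `male_id`, `duration_h`, the
#'   focal observation time available per male and day.
#' @param ages optional tibble with `individual_id`, `date`, `category`
#'   (infant < juvenile < small_subadult < large_subadult < adult); categories
#'   must be non-decreasing over time within an individual.
#' @param meta optional list of configuration metadata carried along.
#'
#' @return An object of class `study_dataset` (a named list of tibbles).
#' @export
#' @examples
#' ds <- simulate_study(sim_config(seed = 1, n_parties = 1, males_per_party = 4,
#'                                 females_per_party = 2, years = 1,
#'                                 sessions_per_year = 10))$dataset
#' ds
study_dataset <- function(individuals, census, sessions, events, coalitions,
                          genotypes = NULL, focals = NULL, ages = NULL,
                          meta = list()) {
  individuals <- tibble::as_tibble(individuals)
  census <- tibble::as_tibble(census)
  sessions <- tibble::as_tibble(sessions)
  events <- tibble::as_tibble(events)
  coalitions <- tibble::as_tibble(coalitions)
  if (!is.null(genotypes)) genotypes <- tibble::as_tibble(genotypes)
  if (!is.null(focals)) focals <- tibble::as_tibble(focals)
  if (!is.null(ages)) ages <- tibble::as_tibble(ages)

  ds <- structure(
    list(individuals = individuals, census = census, sessions = sessions,
         events = events, coalitions = coalitions, genotypes = genotypes,
         focals = focals, ages = ages, meta = meta),
    class = "study_dataset")
  validate_study_dataset(ds)
  ds
}

#' Behaviours recognised in the event table
#' @return character vector of behaviour codes.
#' @export
baboonbonds_behaviours <- function() {
  c("groom", "contact_sit", "approach_1m", "retreat", "greeting",
    "aggression", "copulation")
}

age_category_levels <- function() {
  c("infant", "juvenile", "small_subadult", "large_subadult", "adult")
}

validate_study_dataset <- function(ds) {
  assert_cols(ds$individuals, c("id", "sex", "party", "birth_date", "mother_id"),
              "individuals")
  assert_cols(ds$census, c("date", "individual_id", "party", "present"),
              "census")
  assert_cols(ds$sessions, c("date", "party", "duration_h"), "sessions")
  assert_cols(ds$events,
              c("timestamp", "actor_id", "receiver_id", "behaviour",
                "duration_s", "source", "focal_id"), "events")
  assert_cols(ds$coalitions,
              c("timestamp", "ally1_id", "ally2_id", "target_id", "source"),
              "coalitions")

  if (anyDuplicated(ds$individuals$id)) {
    abort("individuals: duplicated id(s)")
  }
  bad_sex <- setdiff(unique(ds$individuals$sex), c("male", "female"))
  if (length(bad_sex)) abort("individuals: sex must be 'male' or 'female'")

  dup <- ds$census %>% count(.data$date, .data$individual_id) %>%
    filter(n > 1L)
  if (nrow(dup)) {
    abort(sprintf("census: %d individual-date pairs have multiple records",
                  nrow(dup)))
  }
  if (any(ds$sessions$duration_h <= 0)) {
    abort("sessions: duration_h must be > 0")
  }

  bad_beh <- setdiff(unique(ds$events$behaviour), baboonbonds_behaviours())
  if (length(bad_beh)) {
    abort(sprintf("events: unknown behaviour(s): %s",
                  paste(bad_beh, collapse = ", ")))
  }
  if (any(ds$events$actor_id == ds$events$receiver_id)) {
    abort("events: actor_id must differ from receiver_id")
  }
  dur_beh <- ds$events$behaviour %in% c("groom", "contact_sit")
  if (any(ds$events$duration_s[!dur_beh] > 0)) {
    abort("events: duration_s > 0 only allowed for groom/contact_sit")
  }
  if (any(ds$events$duration_s < 0)) abort("events: negative duration_s")

  if (any(ds$coalitions$ally1_id == ds$coalitions$ally2_id)) {
    abort("coalitions: the two allies must differ")
  }
  in_allies <- ds$coalitions$target_id == ds$coalitions$ally1_id |
    ds$coalitions$target_id == ds$coalitions$ally2_id
  if (any(in_allies)) abort("coalitions: target must not be an ally")

  ids <- ds$individuals$id
  check_ids <- function(x, what) {
    bad <- setdiff(unique(x[!is.na(x)]), ids)
    if (length(bad)) {
      abort(sprintf("%s references unknown individual id(s): %s", what,
                    paste(head(bad, 5), collapse = ", ")))
    }
  }
  check_ids(ds$census$individual_id, "census")
  check_ids(ds$events$actor_id, "events (actor)")
  check_ids(ds$events$receiver_id, "events (receiver)")
  check_ids(ds$events$focal_id, "events (focal)")
  check_ids(ds$coalitions$ally1_id, "coalitions")
  check_ids(ds$coalitions$ally2_id, "coalitions")
  check_ids(ds$coalitions$target_id, "coalitions (target)")
  check_ids(ds$individuals$mother_id, "individuals (mother)")
  if (!is.null(ds$genotypes)) {
    assert_cols(ds$genotypes, c("individual_id", "locus", "allele1", "allele2"),
                "genotypes")
    check_ids(ds$genotypes$individual_id, "genotypes")
  }
  if (!is.null(ds$focals)) {
    assert_cols(ds$focals, c("date", "male_id", "duration_h"), "focals")
    check_ids(ds$focals$male_id, "focals")
  }
  if (!is.null(ds$ages)) {
    assert_cols(ds$ages, c("individual_id", "date", "category"), "ages")
    check_ids(ds$ages$individual_id, "ages")
    lv <- age_category_levels()
    bad <- ds$ages %>%
      arrange(.data$individual_id, .data$date) %>%
      group_by(.data$individual_id) %>%
      summarise(ok = !is.unsorted(match(.data$category, lv)),
                .groups = "drop") %>%
      filter(!.data$ok)
    if (nrow(bad)) {
      abort(sprintf("ages: non-monotone age categories for: %s",
                    paste(head(bad$individual_id, 5), collapse = ", ")))
    }
  }
  invisible(ds)
}

#' @export
print.study_dataset <- function(x, ...) {
  yrs <- range(year_of(x$census$date))
  cat("<study_dataset>\n")
  cat(sprintf("  individuals: %d (%d males) in parties: %s\n",
              nrow(x$individuals), sum(x$individuals$sex == "male"),
              paste(sort(unique(x$individuals$party)), collapse = ", ")))
  cat(sprintf("  years %d-%d | %d sessions (%.0f contact h) | %d events | %d coalitions\n",
              yrs[1], yrs[2], nrow(x$sessions), sum(x$sessions$duration_h),
              nrow(x$events), nrow(x$coalitions)))
  if (!is.null(x$genotypes)) {
    cat(sprintf("  genotypes: %d individuals x %d loci\n",
                dplyr::n_distinct(x$genotypes$individual_id),
                dplyr::n_distinct(x$genotypes$locus)))
  }
  invisible(x)
}

study_csv_specs <- function() {
  list(
    individuals = readr::cols(
      id = readr::col_character(), sex = readr::col_character(),
      party = readr::col_character(), birth_date = readr::col_date(),
      mother_id = readr::col_character()),
    census = readr::cols(
      date = readr::col_date(), individual_id = readr::col_character(),
      party = readr::col_character(), present = readr::col_logical(),
      repro_state = readr::col_character()),
    sessions = readr::cols(
      date = readr::col_date(), party = readr::col_character(),
      duration_h = readr::col_double()),
    focals = readr::cols(
      date = readr::col_date(), male_id = readr::col_character(),
      duration_h = readr::col_double()),
    events = readr::cols(
      timestamp = readr::col_datetime(), actor_id = readr::col_character(),
      receiver_id = readr::col_character(), behaviour = readr::col_character(),
      duration_s = readr::col_double(), source = readr::col_character(),
      focal_id = readr::col_character()),
    coalitions = readr::cols(
      timestamp = readr::col_datetime(), ally1_id = readr::col_character(),
      ally2_id = readr::col_character(), target_id = readr::col_character(),
      source = readr::col_character()),
    genotypes = readr::cols(
      individual_id = readr::col_character(), locus = readr::col_character(),
      allele1 = readr::col_integer(), allele2 = readr::col_integer()),
    ages = readr::cols(
      individual_id = readr::col_character(), date = readr::col_date(),
      category = readr::col_character())
  )
}

#' Read a study dataset from CSV files
#'
#' Reads the documented comma-separated, UTF-8, header-row, ISO-8601-date
#' dialect written by [write_study_csv()]. `paths` may be a directory holding
#' `individuals.csv`, `census.csv`, `sessions.csv`, `events.csv`,
#' `coalitions.csv` and optionally `genotypes.csv`, `focals.csv`, `ages.csv`;
#' or a named character vector/list of explicit file paths.
#'
#' @param paths directory or named paths.
#' @return validated [study_dataset()].
#' @export
load_study_csv <- function(paths) {
  specs <- study_csv_specs()
  if (length(paths) == 1L && is.null(names(paths)) && dir.exists(paths)) {
    paths <- setNames(file.path(paths, paste0(names(specs), ".csv")),
                      names(specs))
    paths <- paths[file.exists(paths)]
  }
  need <- c("individuals", "census", "sessions", "events", "coalitions")
  miss <- setdiff(need, names(paths))
  if (length(miss)) {
    abort(sprintf("load_study_csv: missing table(s): %s",
                  paste(miss, collapse = ", ")))
  }
  read_one <- function(name) {
    if (!name %in% names(paths)) return(NULL)
    p <- paths[[name]]
    if (is.null(p) || !file.exists(p)) return(NULL)
    spec <- specs[[name]]
    df <- readr::read_csv(p, col_types = spec, progress = FALSE)
    expected <- names(spec$cols)
    # repro_state is optional in census files
    required <- setdiff(expected, "repro_state")
    assert_cols(df, intersect(required, expected), basename(p))
    df
  }
  tabs <- lapply(setNames(names(specs), names(specs)), read_one)
  study_dataset(individuals = tabs$individuals, census = tabs$census,
                sessions = tabs$sessions, events = tabs$events,
                coalitions = tabs$coalitions, genotypes = tabs$genotypes,
                focals = tabs$focals, ages = tabs$ages)
}

#' Write a study dataset as CSV files
#'
#' @param ds a [study_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_csv <- function(ds, dir) {
  stopifnot(inherits(ds, "study_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (name in c("individuals", "census", "sessions", "events", "coalitions",
                 "genotypes", "focals", "ages")) {
    tab <- ds[[name]]
    if (is.null(tab)) next
    readr::write_csv(tab, file.path(dir, paste0(name, ".csv")), na = "")
  }
  invisible(dir)
}

#' Read genotypes from a GenePop file
#'
#' Parses the classic GenePop text format (title line, one locus name per
#' line or a comma-separated locus line, `Pop` separators, then
#' `id , 001002 003003 ...` records with 2- or 3-digit allele codes;
#' `000`/`00` denotes a missing allele).
#'
#' @param path file path.
#' @return long tibble `individual_id`, `locus`, `allele1`, `allele2`.
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) abort("read_genepop: file too short")
  body <- lines[-1]
  pop_idx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (!length(pop_idx)) abort("read_genepop: no 'Pop' line found")
  locus_lines <- body[seq_len(pop_idx[1] - 1)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  rec_lines <- body[-seq_len(pop_idx[1])]
  rec_lines <- rec_lines[!grepl("^\\s*pop\\s*$", rec_lines, ignore.case = TRUE)]
  parse_rec <- function(line) {
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) < 2) abort("read_genepop: malformed record line")
    id <- trimws(parts[1])
    codes <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(codes) != length(loci)) {
      abort(sprintf("read_genepop: individual %s has %d genotypes for %d loci",
                    id, length(codes), length(loci)))
    }
    w <- nchar(codes[1]) / 2
    a1 <- as.integer(substr(codes, 1, w))
    a2 <- as.integer(substr(codes, w + 1, 2 * w))
    tibble(individual_id = id, locus = loci,
           allele1 = if_else(a1 == 0L, NA_integer_, a1),
           allele2 = if_else(a2 == 0L, NA_integer_, a2))
  }
  purrr::map_dfr(rec_lines, parse_rec)
}

#' Write genotypes to a GenePop file
#'
#' @param genotypes long tibble `individual_id`, `locus`, `allele1`, `allele2`.
#' @param path output path.
#' @param title title line.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(genotypes, path,
                          title = "baboonbonds microsatellite genotypes") {
  assert_cols(genotypes, c("individual_id", "locus", "allele1", "allele2"),
              "genotypes")
  loci <- unique(genotypes$locus)
  wide <- genotypes %>%
    mutate(code = sprintf("%03d%03d",
                          if_else(is.na(.data$allele1), 0L, .data$allele1),
                          if_else(is.na(.data$allele2), 0L, .data$allele2))) %>%
    select("individual_id", "locus", "code") %>%
    tidyr::pivot_wider(names_from = "locus", values_from = "code",
                       values_fill = "000000")
  lines <- c(title, loci, "Pop",
             paste0(wide$individual_id, " ,  ",
                    apply(as.matrix(wide[, loci, drop = FALSE]), 1, paste,
                          collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}
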