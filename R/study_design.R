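# Study design: food-composition bookkeeping, available-carbohydrate portion
# standardization, and per-period randomization of the test diets.

#' Food composition record
#'
#' Macronutrient composition of a cooked (ready-to-eat) staple food, in grams
#' per 100 g. Available carbohydrate is the portion-defining quantity: each
#' test diet serves the staple weight that delivers a fixed mass of available
#' carbohydrate (50 g in the study menus).
#'
#' @param food_code Short label for the food (study foods use letters A-E).
#' @param protein,fat,total_carbohydrate,dietary_fiber,available_carbohydrate
#'   Grams per 100 g cooked food; all must be non-negative and
#'   `available_carbohydrate <= total_carbohydrate`.
#' @return An object of class `food_composition` (a one-row list).
#' @examples
#' food_composition("A", 2.8, 0.2, 35.4, 0.378, 35.0)
#' @export
food_composition <- function(food_code, protein, fat, total_carbohydrate,
                             dietary_fiber, available_carbohydrate) {
  vals <- c(protein = protein, fat = fat,
            total_carbohydrate = total_carbohydrate,
            dietary_fiber = dietary_fiber,
            available_carbohydrate = available_carbohydrate)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop_domain("food '%s': composition values must be finite and >= 0", food_code)
  }
  if (available_carbohydrate > total_carbohydrate + 1e-9) {
    stop_domain("food '%s': available carbohydrate (%g) exceeds total carbohydrate (%g)",
                food_code, available_carbohydrate, total_carbohydrate)
  }
  structure(
    list(food_code = as.character(food_code), protein = protein, fat = fat,
         total_carbohydrate = total_carbohydrate, dietary_fiber = dietary_fiber,
         available_carbohydrate = available_carbohydrate),
    class = "food_composition"
  )
}

#' @export
print.food_composition <- function(x, ...) {
  cat(sprintf("Food '%s' (per 100 g cooked): protein %.2f, fat %.2f, total CHO %.2f, fiber %.3f, available CHO %.2f g\n",
              x$food_code, x$protein, x$fat, x$total_carbohydrate,
              x$dietary_fiber, x$available_carbohydrate))
  invisible(x)
}

#' Read a food-composition table
#'
#' Reads a delimited text file with columns `food_code, protein, fat,
#' total_carbohydrate, dietary_fiber, available_carbohydrate` (g/100 g cooked).
#' The five study staples are shipped as a fixture, see the example.
#'
#' @param path Path to a delimited text file (comma-separated by default).
#' @param sep Field separator.
#' @return A list of [food_composition()] objects, named by food code.
#' @examples
#' tab <- system.file("extdata", "food_composition.csv", package = "nof1ppgr")
#' comps <- read_composition(tab)
#' names(comps)
#' @export
read_composition <- function(path, sep = ",") {
  if (!file.exists(path)) stop_domain("composition table not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  needed <- c("food_code", "protein", "fat", "total_carbohydrate",
              "dietary_fiber", "available_carbohydrate")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop_domain("composition table %s lacks columns: %s", path,
                paste(missing, collapse = ", "))
  }
  comps <- lapply(seq_len(nrow(df)), function(i) {
    food_composition(df$food_code[i], df$protein[i], df$fat[i],
                     df$total_carbohydrate[i], df$dietary_fiber[i],
                     df$available_carbohydrate[i])
  })
  names(comps) <- vapply(comps, `[[`, "", "food_code")
  comps
}

#' Staple portion weight for an available-carbohydrate target
#'
#' Computes the cooked staple weight delivering `target_available_carb` grams
#' of available carbohydrate: `100 * target / available_carbohydrate`, rounded
#' half-away-from-zero to the nearest gram (the rounding that reproduces all
#' five study menu weights).
#'
#' @param target_available_carb Target available carbohydrate, grams (> 0).
#' @param comp A [food_composition()].
#' @return Portion weight in grams (whole number).
#' @examples
#' rice <- food_composition("A", 2.8, 0.2, 35.4, 0.378, 35.0)
#' portion_weight(50, rice)  # 143 g
#' @export
portion_weight <- function(target_available_carb, comp) {
  stopifnot(inherits(comp, "food_composition"))
  if (!is.finite(target_available_carb) || target_available_carb <= 0) {
    stop_domain("target available carbohydrate must be > 0 (got %g)",
                target_available_carb)
  }
  if (comp$available_carbohydrate <= 0) {
    stop_domain("food '%s': available carbohydrate must be > 0 to compute a portion",
                comp$food_code)
  }
  as.numeric(round_half_up(100 * target_available_carb / comp$available_carbohydrate))
}

# Side items served identically with every staple.
default_side_items <- function() {
  data.frame(item = c("eggs_tomato_g", "cucumber_g", "milk_mL"),
             amount = c(150, 50, 200), stringsAsFactors = FALSE)
}

#' Build the standardized test-diet menu
#'
#' One row per staple food, with the staple weight standardized to the
#' available-carbohydrate target and the fixed side items (150 g scrambled
#' eggs with tomatoes, 50 g cucumber, 200 mL milk) attached to every row.
#'
#' @param comps List of [food_composition()] objects (may be empty).
#' @param target_available_carb Grams of available carbohydrate per serving.
#' @param side_items Data frame of fixed side items (item, amount); identical
#'   for all rows.
#' @return A data frame with columns `food_code`, `staple_weight_g`, and one
#'   column per side item.
#' @examples
#' tab <- system.file("extdata", "food_composition.csv", package = "nof1ppgr")
#' build_menu(read_composition(tab), 50)
#' @export
build_menu <- function(comps, target_available_carb = 50,
                       side_items = default_side_items()) {
  if (length(comps) == 0) {
    out <- data.frame(food_code = character(0), staple_weight_g = numeric(0))
    for (it in side_items$item) out[[it]] <- numeric(0)
    return(out)
  }
  out <- data.frame(
    food_code = vapply(comps, `[[`, "", "food_code"),
    staple_weight_g = vapply(comps, function(cc)
      portion_weight(target_available_carb, cc), 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
  for (i in seq_len(nrow(side_items))) out[[side_items$item[i]]] <- side_items$amount[i]
  out
}

#' Randomized crossover design plan
#'
#' Generates, for every participant and period, an independent uniformly
#' random ordering of the test foods (each food served exactly once per
#' period). The seed is stored in the plan so the allocation is reproducible;
#' per-participant sequences can be exported separately for concealment.
#'
#' @param participant_ids Vector of participant identifiers.
#' @param n_periods Number of crossover periods (study default 3).
#' @param food_codes Distinct food codes (study default `LETTERS[1:5]`).
#' @param seed Integer RNG seed recorded in the plan.
#' @return An object of class `design_plan`: a list with `sequences` (data
#'   frame `participant_id, period, slot, food_code`), `participant_ids`,
#'   `n_periods`, `food_codes` and `seed`.
#' @examples
#' plan <- randomize_plan(paste0("P", 1:3), seed = 1)
#' head(plan$sequences)
#' @export
randomize_plan <- function(participant_ids, n_periods = 3,
                           food_codes = LETTERS[1:5], seed) {
  if (n_periods < 1) stop_domain("n_periods must be >= 1")
  food_codes <- as.character(food_codes)
  if (length(food_codes) == 0) stop_domain("food_codes must be nonempty")
  if (anyDuplicated(food_codes)) {
    stop_domain("duplicate food codes: %s",
                paste(unique(food_codes[duplicated(food_codes)]), collapse = ", "))
  }
  participant_ids <- as.character(participant_ids)
  k <- length(food_codes)
  n_seq <- length(participant_ids) * n_periods
  codes <- with_seed(seed, {
    # one independent uniform permutation per (participant, period)
    as.vector(vapply(seq_len(n_seq), function(i) sample(food_codes, k),
                     character(k)))
  })
  seqs <- data.frame(
    participant_id = rep(participant_ids, each = n_periods * k),
    period = rep(rep(seq_len(n_periods), each = k), length(participant_ids)),
    slot = rep(seq_len(k), n_seq),
    food_code = codes,
    stringsAsFactors = FALSE
  )
  structure(
    list(sequences = seqs, participant_ids = participant_ids,
         n_periods = n_periods, food_codes = food_codes, seed = seed),
    class = "design_plan"
  )
}

#' @export
print.design_plan <- function(x, ...) {
  cat(sprintf("Crossover design plan: %d participants x %d periods x %d foods (seed %s)\n",
              length(x$participant_ids), x$n_periods, length(x$food_codes),
              format(x$seed)))
  invisible(x)
}

#' Export a design plan
#'
#' Writes the allocation as delimited text (`participant_id,period,slot,
#' food_code`) plus a JSON sidecar recording the seed and generation time.
#'
#' @param plan A [randomize_plan()] result.
#' @param path Output path for the delimited plan; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @param sep Field separator.
#' @return Invisibly, the paths written.
#' @export
write_plan <- function(plan, path, sep = ",") {
  stopifnot(inherits(plan, "design_plan"))
  utils::write.table(plan$sequences, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(seed = plan$seed, n_periods = plan$n_periods,
         food_codes = plan$food_codes,
         generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    sidecar, auto_unbox = TRUE
  )
  invisible(c(plan = path, sidecar = sidecar))
}
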