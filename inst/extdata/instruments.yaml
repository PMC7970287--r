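# Instrument dictionaries: item ids, legal codes, subscale membership.
# Version 1. Item wording is paraphrased field shorthand; the CDI word
# lists are synthetic placeholders (w001..w100) because the adapted
# Bangla inventory is not public.
version: 1
fci:
  activities:            # caregiver-report, previous 3 days, binary
    - read_books
    - told_stories
    - sang_songs
    - taken_outside
    - played_with
    - named_counted_drew
  materials:             # observed play-material varieties, binary
    - things_making_music
    - things_drawing_writing
    - picture_books
    - things_that_move
    - toys_building
    - household_objects
  observation:           # responsiveness + home-environment items, binary
    - caregiver_responds_vocally
    - caregiver_answers_questions
    - caregiver_praises_child
    - caregiver_caresses_child
    - caregiver_talks_during_tasks
    - caregiver_within_view
    - child_can_reach_toys
    - caregiver_structures_play
    - caregiver_no_harsh_voice
    - home_safe_sharp_objects
    - home_safe_fall_hazards
  codes: [0, 1]
asqi:
  domains:
    - communication
    - gross_motor
    - fine_motor
    - problem_solving
    - personal_social
  items_per_domain: 6
  codes: ["yes", "sometimes", "not_yet"]
  default_scheme: {"yes": 10, "sometimes": 5, "not_yet": 0}
cesd:
  n_items: 20
  codes: [0, 1, 2, 3]
  # positively-worded items, reverse-coded per the standard key
  reverse_items: [4, 8, 12, 16]
cdi:
  # synthetic 100-word inventories (real adapted list not public)
  n_receptive: 100
  n_expressive: 100
  codes: [0, 1]
  expressive_min_age_months: 9
diet:
  maternal_groups:       # MDD-W, 10 groups, threshold >= 5
    - grains
    - legumes
    - nuts_seeds
    - dairy
    - flesh_foods
    - eggs
    - vitamin_a_fruits_vegetables
    - other_vitamin_a_fruits_vegetables
    - other_vegetables
    - other_fruits
  maternal_threshold: 5
  child_groups:          # child MDD, 8 groups incl. breastmilk, >= 5
    - breastmilk
    - grains
    - legumes
    - dairy
    - flesh_foods
    - eggs
    - vitamin_a_fruits_vegetables
    - other_fruits_vegetables
  child_threshold: 5
  child_min_age_months: 6
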