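# Refinement rules layered on top of the ontology lexicons.
# These cover the context-dependent abbreviations that plain dictionary
# matching cannot resolve: single-letter laterality, "SL", and the
# apostrophe (minutes vs feet) convention.
version: "1.0"

context_rules:
  # "L knee" -> left; "R knee" -> right. The single letter maps to a side
  # only when the very next token is a body-location word; "L5" (machine
  # resistance level) and free-standing letters never match.
  single_letter_side:
    enabled: true
    letters: {L: side.left, R: side.right}
  # "SL" reads as single-leg (-> unilateral laterality) when followed by a
  # limb/stance word, and as side-lying (a posture; not an ontology concept)
  # otherwise. Bare "A" for anterior is deliberately never matched.
  sl_single_leg:
    enabled: true
    concept: side.unilateral
    followers: [leg, stance, squat, stand, raise, hop, balance, bridge]

numeric_rules:
  # N' is minutes (-> seconds) unless a locomotion word appears shortly
  # before it, in which case it is a distance in feet. Distances are
  # recognized and logged but emitted as annotations only, never as
  # duration findings.
  apostrophe_locomotion_words: [walk, walks, walked, walking, gait, stepping, ambulation, ambulating, ambulate]
  apostrophe_context_chars: 30

status_rules:
  # Precedence: not-performed markers outrank HEP markers outrank the
  # in-office default.
  precedence: [desc.not_performed, desc.hep, desc.in_office]

placeholders:
  # Deidentification placeholders are opaque single tokens; nothing inside
  # them may fire a rule.
  pattern: "\\[[A-Z]+\\]"
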