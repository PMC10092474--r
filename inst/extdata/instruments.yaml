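# Instrument definitions.
#
# IDQ / IAQ: self-report measures aligned with the ICD-11 descriptions of
# Depressive Episode (6A70) and Generalized Anxiety Disorder (6B00).
# Response anchors (both scales): 0 Never / 1 Only a few days /
# 2 Half the days / 3 Most days / 4 Every day.  An item is "endorsed" when
# the response is Most days (3) or Every day (4).  Caseness additionally
# requires a "Yes" to the functional-impairment question.
#
# PHQ-9 / GAD-7: DSM-IV-aligned comparators scored 0-3 per item with the
# conventional screening cut-off of >= 10 on the sum score; item texts are
# not redistributed here.
idq:
  name: International Depression Questionnaire
  abbreviation: IDQ
  timeframe: Over the last two weeks
  anchors: [Never, Only a few days, Half the days, Most days, Every day]
  max_response: 4
  endorsement_threshold: 3
  core_items: [1, 2]
  min_endorsed: 5
  impairment_item: >-
    Have these experiences caused problems in personal, family, social,
    educational, occupational, or other important areas of your life?
  items:
    - Felt down or depressed for most of the day?
    - Experienced less interest or pleasure from normal activities for most of the day?
    - Have had difficulty concentrating?
    - Had feelings of worthlessness or guilt?
    - Felt hopeless?
    - Had recurrent thoughts of death or suicide?
    - Have had changes in appetite or sleep?
    - Moved slower or felt more restless?
    - Experienced reduced energy or fatigue?
iaq:
  name: International Anxiety Questionnaire
  abbreviation: IAQ
  timeframe: Over the last several months
  anchors: [Never, Only a few days, Half the days, Most days, Every day]
  max_response: 4
  endorsement_threshold: 3
  core_items: [1, 2]
  min_endorsed: 4
  impairment_item: >-
    Have these experiences caused problems in personal, family, social,
    educational, occupational, or other important areas of your life?
  items:
    - Felt nervous or anxious?
    - Worried a lot about different things?
    - Felt physically tense or agitated?
    - Felt your heart racing, difficulty breathing, stomach discomfort, or dry mouth?
    - Felt "on edge"?
    - Had difficulty concentrating?
    - Been easily annoyed by different things?
    - Experienced sleep disturbances?
phq9:
  name: Patient Health Questionnaire-9
  abbreviation: PHQ-9
  n_items: 9
  max_response: 3
  cutoff: 10
gad7:
  name: Generalized Anxiety Disorder-7
  abbreviation: GAD-7
  n_items: 7
  max_response: 3
  cutoff: 10
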