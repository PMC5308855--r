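# Demonstration pipeline configuration: a synthetic database emulating a
# rare, male-skewed adverse event concentrated in chemotherapy regimens.
output_dir: rorscreen_demo
event_term: hiccups
stratify_drug: dexamethasone
anticancer_drugs:
  - oxaliplatin
  - fluorouracil
  - cisplatin
min_reports: 3
alpha: 0.05
ci_level: 0.95
seed: 2016
synthetic:
  n_cases: 30000
  background_event_rate: 0.002
  male_odds_multiplier: 10
  duplicate_fraction: 0.05
  seed: 2016
  drugs:
    - name: dexamethasone
      prevalence: 0.02
      event_odds_multiplier: 8
      route_distribution:
        intravenous: 0.4
        oral: 0.5
        other: 0.1
    - name: oxaliplatin
      prevalence: 0.03
      event_odds_multiplier: 4
    - name: fluorouracil
      prevalence: 0.03
      event_odds_multiplier: 3
    - name: cisplatin
      prevalence: 0.02
      event_odds_multiplier: 2
    - name: famotidine
      prevalence: 0.05
      event_odds_multiplier: 1
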