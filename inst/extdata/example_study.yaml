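study: DEMO
sources:
  patients:
    path: patients.csv
    role: patient-file
    key_columns: [PatientID]
  labs:
    path: labs.csv
    role: data-file
    key_columns: [PatientID]
    timestamp_column: Date
entities:
  - name: Demographics
    anchor: patient
    source: patients
    attributes:
      - {name: Sex, column: Sex}
      - {name: YearOfBirth, column: YearOfBirth, type: numeric}
  - name: Laboratory
    anchor: patient
    source: labs
    eav:
      parameter_columns: [Parameter]
      value_column: Result
      meta_columns:
        - {name: Unit, column: Unit}
        - {name: Norm range, column: NormRange}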