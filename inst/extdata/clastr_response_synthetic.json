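{
  "description": "QUERY1",
  "cellosaurusRelease": "synthetic-fixture",
  "runOn": "2026-01-01T00:00:00",
  "toolVersion": "1.4.4",
  "searchSpace": 8581,
  "parameters": {
    "algorithm": 1,
    "scoringMode": 1,
    "scoreFilter": 70,
    "includeAmelogenin": false,
    "maxResults": 200
  },
  "results": [
    {
      "accession": "CVCL_0000",
      "name": "SyntheticLine-A",
      "species": "Homo sapiens",
      "bestScore": 100.0,
      "problem": "Contaminated. Shown to be a synthetic fixture line.",
      "profiles": [
        {
          "score": 100.0,
          "markerNumber": 5,
          "alleleNumber": 9,
          "markers": [
            {
              "name": "Amelogenin",
              "conflicted": false,
              "searched": true,
              "alleles": [
                {"value": "X", "matched": true}
              ]
            },
            {
              "name": "CSF1PO",
              "conflicted": false,
              "searched": true,
              "alleles": [
                {"value": "11", "matched": true},
                {"value": "12", "matched": true}
              ]
            },
            {
              "name": "D5S818",
              "conflicted": false,
              "searched": true,
              "alleles": [
                {"value": "11", "matched": true},
                {"value": "13", "matched": true}
              ]
            },
            {
              "name": "TH01",
              "conflicted": false,
              "searched": true,
              "alleles": [
                {"value": "6", "matched": true},
                {"value": "9.3", "matched": true}
              ]
            },
            {
              "name": "vWA",
              "conflicted": false,
              "searched": true,
              "alleles": [
                {"value": "17", "matched": true},
                {"value": "18", "matched": true}
              ]
            }
          ]
        }
      ]
    },
    {
      "accession": "CVCL_0001",
      "name": "SyntheticLine-B",
      "species": "Homo sapiens",
      "bestScore": 87.5,
      "profiles": [
        {
          "score": 87.5,
          "markerNumber": 4,
          "alleleNumber": 8,
          "markers": [
            {
              "name": "CSF1PO",
              "conflicted": false,
              "searched": true,
              "alleles": [
                {"value": "11", "matched": true},
                {"value": "12", "matched": true}
              ]
            },
            {
              "name": "D5S818",
              "conflicted": false,
              "searched": true,
              "alleles": [
                {"value": "11", "matched": true},
                {"value": "12", "matched": false}
              ]
            },
            {
              "name": "TH01",
              "conflicted": false,
              "searched": true,
              "alleles": [
                {"value": "6", "matched": true},
                {"value": "9.3", "matched": true}
              ]
            },
            {
              "name": "vWA",
              "conflicted": false,
              "searched": true,
              "alleles": [
                {"value": "17", "matched": true},
                {"value": "18", "matched": true}
              ]
            }
          ]
        }
      ]
    },
    {
      "accession": "CVCL_0002",
      "name": "SyntheticLine-C",
      "species": "Homo sapiens",
      "bestScore": 72.0,
      "profiles": [
        {
          "score": 72.0,
          "markerNumber": 3,
          "alleleNumber": 6,
          "markers": [
            {
              "name": "CSF1PO",
              "conflicted": false,
              "searched": true,
              "alleles": [
                {"value": "10", "matched": false},
                {"value": "12", "matched": true}
              ]
            },
            {
              "name": "TH01",
              "conflicted": false,
              "searched": true,
              "alleles": [
                {"value": "6", "matched": true},
                {"value": "7", "matched": false}
              ]
            },
            {
              "name": "vWA",
              "conflicted": false,
              "searched": true,
              "alleles": [
                {"value": "17", "matched": true},
                {"value": "18", "matched": true}
              ]
            }
          ]
        }
      ]
    }
  ]
}
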