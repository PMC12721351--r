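threshold,heart,lung,liver,kidney
25,6227941.79,3094439.23,4523546.12,9925.36
50,6208442.85,3079895.36,4488056.06,24104.43
100,6125572.32,3026567.85,4356742.87,79402.84
150,5998829.17,2936880.67,4175743.60,161641.50
200,5813589.17,2810833.82,3945058.26,282163.67
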