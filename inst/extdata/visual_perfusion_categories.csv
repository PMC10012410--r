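"subject_id","cohort","category"
"ictal-01","ictal","hyperperfusion"
"ictal-02","ictal","hyperperfusion"
"ictal-03","ictal","hyperperfusion"
"ictal-04","ictal","hyperperfusion"
"ictal-05","ictal","hyperperfusion"
"ictal-06","ictal","hyperperfusion"
"ictal-07","ictal","hyperperfusion"
"ictal-08","ictal","hyperperfusion"
"ictal-09","ictal","hyperperfusion"
"ictal-10","ictal","hyperperfusion"
"ictal-11","ictal","hyperperfusion"
"ictal-12","ictal","hyperperfusion"
"ictal-13","ictal","hyperperfusion"
"ictal-14","ictal","hyperperfusion"
"ictal-15","ictal","hyperperfusion"
"ictal-16","ictal","hyperperfusion"
"ictal-17","ictal","hyperperfusion"
"ictal-18","ictal","hypoperfusion"
"postictal-01","postictal","normal"
"postictal-02","postictal","normal"
"postictal-03","postictal","normal"
"postictal-04","postictal","normal"
"postictal-05","postictal","normal"
"postictal-06","postictal","normal"
"postictal-07","postictal","normal"
"postictal-08","postictal","normal"
"postictal-09","postictal","normal"
"postictal-10","postictal","normal"
"postictal-11","postictal","normal"
"postictal-12","postictal","normal"
"postictal-13","postictal","normal"
"postictal-14","postictal","normal"
"postictal-15","postictal","normal"
"postictal-16","postictal","normal"
"postictal-17","postictal","normal"
"postictal-18","postictal","normal"
"postictal-19","postictal","normal"
"postictal-20","postictal","normal"
"postictal-21","postictal","normal"
"postictal-22","postictal","normal"
"postictal-23","postictal","normal"
"postictal-24","postictal","normal"
"postictal-25","postictal","hypoperfusion"
"postictal-26","postictal","hypoperfusion"
"postictal-27","postictal","hypoperfusion"
"postictal-28","postictal","hypoperfusion"
"postictal-29","postictal","hypoperfusion"
"postictal-30","postictal","hypoperfusion"
"postictal-31","postictal","hypoperfusion"
"postictal-32","postictal","hypoperfusion"
"postictal-33","postictal","hypoperfusion"
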