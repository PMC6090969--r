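population,treatment,arm,drug,administration,health_state,indirect,adverse_event,total_cost,total_qalys
conventional_care_failure,ustekinumab,intervention,50352,312,55127,111987,14447,232225,14.275
conventional_care_failure,adalimumab,comparator,41942,996,57767,118962,19543,239209,14.043
tnf_failure,ustekinumab,intervention,43501,336,61206,128843,14859,248745,14.180
tnf_failure,vedolizumab,comparator,31885,2293,62767,132895,14881,244721,14.047
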