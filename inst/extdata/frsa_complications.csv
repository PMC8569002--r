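case_index,description,severity,months_from_surgery,attributable,revision_surgery,long_term_medication,outcome_compromised
3,Radial nerve palsy; complete recovery after 6 weeks,minor,0,TRUE,FALSE,FALSE,FALSE
5,Axillary nerve palsy; persistent paresthesia after 12 months,minor,0,TRUE,FALSE,FALSE,FALSE
9,Radial nerve palsy; complete recovery after 6 weeks,minor,0,TRUE,FALSE,FALSE,FALSE
14,Pain from cerclage cable lock; cable removed,minor,7,TRUE,FALSE,FALSE,FALSE
18,Impingement from cerclage cable lock; cable removed,minor,11,TRUE,FALSE,FALSE,FALSE
22,Pain from cerclage cable lock; cable removed,minor,8,TRUE,FALSE,FALSE,FALSE
7,Subacromial impingement; subacromial decompression and acromioplasty,major,3,TRUE,TRUE,FALSE,FALSE
11,Aseptic loosening of the humeral stem; revision,major,7,TRUE,TRUE,FALSE,TRUE
16,Shoulder dislocation; open shoulder reduction,major,1,TRUE,TRUE,FALSE,FALSE
26,Periprosthetic fracture after post-operative fall; open reduction and internal fixation,major,2,FALSE,TRUE,FALSE,FALSE
31,Shoulder dislocation after post-operative fall; no pain and surgery declined,minor,5,FALSE,FALSE,FALSE,FALSE
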