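variable,level,none,some,more
gender,men,958,1268,679
gender,women,497,1186,1555
economic_activity,active,982,1617,1103
economic_activity,inactive,472,827,1120
occupational_grade,professional_managerial,444,920,736
occupational_grade,intermediate,381,695,629
occupational_grade,routine_semiroutine,407,611,616
occupational_grade,not_applicable,217,226,251
children_under_16,yes,524,794,717
children_under_16,no,931,1660,1517
education,still_in_education,333,421,228
education,age_16_or_under,547,891,982
education,over_16,575,1142,1024
day_type,weekday,720,1304,1069
day_type,weekend,735,1150,1165
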