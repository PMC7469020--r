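code,part,is_foodwork
pcare_wash,personal_care,FALSE
pcare_groom,personal_care,FALSE
sleep_bed,sleep,FALSE
sleep_rest,sleep,FALSE
eat_meal,eating,FALSE
eat_snack,eating,FALSE
pa_walk,physical_activity,FALSE
pa_sport,physical_activity,FALSE
screen_tv,screen_time,FALSE
screen_computer,screen_time,FALSE
work_paid,work,FALSE
work_house,work,FALSE
work_care,work,FALSE
food_shop,work,TRUE
food_prep,work,TRUE
food_dishes,work,TRUE
social_visit,social_hobbies,FALSE
social_phone,social_hobbies,FALSE
hobby_craft,social_hobbies,FALSE
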