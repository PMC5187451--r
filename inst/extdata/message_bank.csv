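level,trigger_or_category,message_id,text
L0,none,L0-001,Quitting smoking is the single best thing you can do for your health. Your quit day is coming - start planning now.
L0,none,L0-002,It's OK to have mixed feelings about quitting. Don't let that stop you!
L0,none,L0-003,Make a list of your reasons for quitting and keep it with you.
L0,none,L0-004,Tell your friends and family about your quit date. Support makes quitting easier.
L0,none,L0-005,Throw away ashtrays and lighters before your quit day so cigarettes are harder to reach.
L0,none,L0-006,Notice when and where you smoke. Knowing your patterns helps you plan ways to cope.
L0,none,L0-007,If you were prescribed a quit-smoking medication - start taking it as directed.
L0,none,L0-008,Plan something to do with your hands and your mouth - gum or a straw can help in the first days.
L0,none,L0-009,Think of a past quit attempt. What worked? What will you do differently this time?
L0,none,L0-010,You are almost there. Stock up on healthy snacks and plan rewards for your first smoke-free days.
L1,none,L1-001,Great job staying quit! Every hour smoke-free is a win.
L1,none,L1-002,Remind yourself why you quit. Your reasons are still true today.
L1,none,L1-003,Ask a friend to check in on you today. Social support helps people stay quit.
L1,none,L1-004,Your body is already healing. Breathing gets easier every smoke-free day.
L1,none,L1-005,Plan ahead: what will you do the next time an urge shows up?
L1,none,L1-006,Keep busy! Activity is one of the best ways to keep your mind off smoking.
L2,stress_affect,L2-SA-001,Stress fades whether or not you smoke. Try slow deep breaths - in for 4 and out for 6 - until it passes.
L2,stress_affect,L2-SA-002,Feeling down or tense is a common trigger. Step away from the situation and take a short walk.
L2,stress_affect,L2-SA-003,A cigarette won't fix the stress. Call someone who supports your quit and talk it through.
L2,urge,L2-UR-001,Urges peak and pass within a few minutes. Ride it out - it WILL fade.
L2,urge,L2-UR-002,Do something with your hands right now. Urges fade fastest when you are busy.
L2,urge,L2-UR-003,Drink a glass of water slowly and the urge will pass whether or not you smoke.
L2,availability,L2-AV-001,Cigarettes within reach make slips easy. Get rid of them now - give them away or destroy them.
L2,availability,L2-AV-002,Make smoking harder: leave the cigarettes behind and go somewhere smoke-free.
L2,availability,L2-AV-003,Ask the people around you not to offer cigarettes and to keep theirs out of sight.
L2,motivation,L2-MO-001,Motivation comes and goes - commitment keeps you quit. Reread your reasons for quitting.
L2,motivation,L2-MO-002,Think about how far you have come. Don't let one hard moment undo it.
L2,motivation,L2-MO-003,Picture the payoff: more money and better health and freedom from cigarettes.
L3,none,L3-001,A slip is a sign that you need to improve your smoking cessation plan. Think about what went wrong and develop a stronger plan to stay quit. Keep trying and YOU WILL SUCCEED!
L3,none,L3-002,One slip does not make you a smoker again. Get back on track right now.
L3,none,L3-003,Many successful quitters slipped along the way. What matters is what you do next.
L3,none,L3-004,Throw out any remaining cigarettes and recommit to your quit - starting this minute.
L3,none,L3-005,Learn from the slip: what was the trigger? Plan how you will handle it next time.
quit_tips,general_advice,QT-GA-001,Set small goals: get through the next hour smoke-free and then the next.
quit_tips,general_advice,QT-GA-002,Change your routine - take a different route and sit in a different chair.
quit_tips,general_advice,QT-GA-003,Keep your quit-smoking medication with you and use it as directed.
quit_tips,benefits,QT-BE-001,Within days of quitting your sense of taste and smell improve.
quit_tips,benefits,QT-BE-002,Quitting cuts your risk of heart attack - starting within 24 hours.
quit_tips,benefits,QT-BE-003,A pack-a-day smoker saves thousands of dollars a year by quitting.
quit_tips,coping_urges,QT-CU-001,Delay! Urges pass in a few minutes whether or not you smoke.
quit_tips,coping_urges,QT-CU-002,Deep breathing: breathe in slowly and out slowly ten times.
quit_tips,coping_urges,QT-CU-003,Drink water and keep sugar-free gum handy for sudden urges.
quit_tips,coping_stress,QT-CS-001,Tense then relax each muscle group from your toes to your head.
quit_tips,coping_stress,QT-CS-002,A ten-minute walk lowers stress more reliably than a cigarette.
quit_tips,coping_stress,QT-CS-003,Write down what is stressing you and one small step you can take.
quit_tips,coping_mood,QT-CM-001,Low mood after quitting is common and temporary. Be kind to yourself.
quit_tips,coping_mood,QT-CM-002,Do one thing you enjoy today - you earned it by staying quit.
quit_tips,coping_mood,QT-CM-003,Talk to someone. Sharing how you feel beats smoking about it.
medication_tips,varenicline,MT-VA-001,Take varenicline (Chantix) with food and a full glass of water to reduce nausea.
medication_tips,varenicline,MT-VA-002,Varenicline roughly doubles or triples your chances of quitting versus willpower alone.
medication_tips,varenicline,MT-VA-003,Keep taking varenicline even after you feel confident - finishing the course protects your quit.
medication_tips,patch,MT-PA-001,Apply the nicotine patch to clean dry skin each morning and rotate sites.
medication_tips,patch,MT-PA-002,If you have vivid dreams - remove the patch at bedtime and put a fresh one on in the morning.
medication_tips,patch,MT-PA-003,The patch gives steady nicotine. Add gum for breakthrough urges if prescribed.
medication_tips,gum,MT-GU-001,Use the bite-and-park method: chew until tingling then park the gum in your cheek.
medication_tips,gum,MT-GU-002,Avoid coffee or soda 15 minutes before nicotine gum - acid blocks absorption.
medication_tips,gum,MT-GU-003,Use gum on a schedule in the first weeks rather than waiting for strong urges.
medication_tips,bupropion,MT-BU-001,Bupropion (Zyban) works best started 1-2 weeks before your quit date.
medication_tips,bupropion,MT-BU-002,Take bupropion doses at least 8 hours apart and avoid a dose near bedtime.
medication_tips,bupropion,MT-BU-003,Bupropion reduces urges and withdrawal and can be combined with the patch if prescribed.
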